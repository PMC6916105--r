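{
  "__comment": "Best-effort dialect for Varscan-style VCFs (RD/AD depth fields; DP4 strand counts ref_fwd,ref_rev,alt_fwd,alt_rev).",
  "tumor_sample": "TUMOR",
  "normal_sample": "NORMAL",
  "fields": [
    {"name": "t_rd", "kind": "format", "key": "RD", "sample": "tumor"},
    {"name": "t_ad", "kind": "format", "key": "AD", "sample": "tumor"}
  ],
  "filters": [
    {
      "name": "tumor_vaf",
      "source": {"kind": "expr", "expr": "t_ad / (t_rd + t_ad)"},
      "direction": "keep_if_at_least",
      "type": "real",
      "enabled": true,
      "missing_policy": "fail_filter"
    },
    {
      "name": "tumor_depth",
      "source": {"kind": "format", "key": "DP", "sample": "tumor"},
      "direction": "keep_if_at_least",
      "type": "integer",
      "enabled": true,
      "missing_policy": "fail_filter"
    },
    {
      "name": "tumor_ref_dp",
      "source": {"kind": "format", "key": "RD", "sample": "tumor"},
      "direction": "keep_if_at_least",
      "type": "integer",
      "enabled": true,
      "missing_policy": "fail_filter"
    }
  ],
  "strand_counts": {"kind": "format", "key": "DP4", "sample": "tumor"}
}
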