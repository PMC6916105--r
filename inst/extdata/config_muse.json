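{
  "__comment": "Best-effort dialect for Muse-style VCFs (no FORMAT AF; VAF derived from allelic depths).",
  "tumor_sample": "TUMOR",
  "normal_sample": "NORMAL",
  "fields": [
    {"name": "t_ref_dp", "kind": "format", "key": "AD", "index": 1, "sample": "tumor"},
    {"name": "t_alt_dp", "kind": "format", "key": "AD", "index": 2, "sample": "tumor"}
  ],
  "filters": [
    {
      "name": "tumor_vaf",
      "source": {"kind": "expr", "expr": "t_alt_dp / (t_ref_dp + t_alt_dp)"},
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
      "name": "tumor_alt_dp",
      "source": {"kind": "format", "key": "AD", "index": 2, "sample": "tumor"},
      "direction": "keep_if_at_least",
      "type": "integer",
      "enabled": true,
      "missing_policy": "fail_filter"
    }
  ]
}
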