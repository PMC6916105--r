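{
  "__comment": "Best-effort dialect for MuTect2-style VCFs; field availability varies by caller version, adjust to your files.",
  "tumor_sample": "TUMOR",
  "normal_sample": "NORMAL",
  "fields": [],
  "filters": [
    {
      "name": "tumor_vaf",
      "source": {"kind": "format", "key": "AF", "sample": "tumor"},
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
      "source": {"kind": "format", "key": "AD", "index": 1, "sample": "tumor"},
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
    },
    {
      "name": "normal_vaf",
      "source": {"kind": "format", "key": "AF", "sample": "normal"},
      "direction": "keep_if_at_most",
      "type": "real",
      "enabled": true,
      "missing_policy": "pass_filter"
    }
  ]
}
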