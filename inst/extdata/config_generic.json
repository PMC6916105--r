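{
  "tumor_sample": "TUMOR",
  "normal_sample": "NORMAL",
  "fields": [],
  "filters": [
    {
      "name": "vaf",
      "source": {"kind": "format", "key": "AF", "sample": "tumor"},
      "direction": "keep_if_at_least",
      "type": "real",
      "enabled": true,
      "missing_policy": "fail_filter"
    },
    {
      "name": "bq",
      "source": {"kind": "info", "key": "BQ"},
      "direction": "keep_if_at_least",
      "type": "real",
      "enabled": true,
      "missing_policy": "fail_filter"
    }
  ],
  "strand_counts": {"kind": "format", "key": "SC", "sample": "tumor"}
}
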