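{
  "name": "euro_cmr_score_bands",
  "description": "Paired per-patient modified EuroCMR artifact scores, published banded (0, 1-3, 4-6, 7-10; lower is better). Reference segmented cine in rows, real-time compressed-sensing cine in columns; counts for 71 patients. Band indices 0-3 stand in for per-patient raw scores, which were not published.",
  "labels": ["0", "1-3", "4-6", "7-10"],
  "values": [0, 1, 2, 3],
  "higher_is_better": false,
  "counts": [
    [1, 1, 0, 0],
    [25, 42, 2, 0],
    [0, 0, 0, 0],
    [0, 0, 0, 0]
  ],
  "printed": {
    "n": 71,
    "median_ref_raw_scale": 3,
    "range_ref_raw_scale": [0, 3],
    "median_rt_raw_scale": 1,
    "range_rt_raw_scale": [0, 5],
    "medians_on_raw_scale": true,
    "equal_or_better_n": 68,
    "equal_or_better_pct": 95.8,
    "p_label": "<0.0001"
  }
}
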