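{
  "name": "subjective_overall_quality",
  "description": "Paired per-patient subjective overall image quality (4-point Likert: 1 non-diagnostic, 2 poor, 3 good, 4 excellent). Reference segmented cine in rows, real-time compressed-sensing cine in columns; published cross-tabulation counts for 71 patients.",
  "labels": ["1", "2", "3", "4"],
  "values": [1, 2, 3, 4],
  "higher_is_better": true,
  "counts": [
    [5, 3, 15, 0],
    [5, 6, 21, 0],
    [0, 2, 13, 0],
    [0, 0, 1, 0]
  ],
  "printed": {
    "n": 71,
    "median_ref": 2,
    "range_ref": [1, 4],
    "median_rt": 3,
    "range_rt": [1, 3],
    "equal_or_better_n": 64,
    "equal_or_better_pct": 90.1,
    "p_label": "<0.0001"
  }
}
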