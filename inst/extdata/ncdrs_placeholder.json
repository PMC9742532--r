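{
  "name": "NCDRS-schema placeholder",
  "description": "PLACEHOLDER point values in the New Chinese Diabetes Risk Score schema. The published point table is cited, not printed, in the source study; edit this file to use the official values. Only the screen-positive cutoff (25) is the published one. Feature coding: sex 1 = male.",
  "cutoff": 25,
  "items": [
    {"feature": "age", "breaks": [40, 45, 50, 55, 60, 65], "points": [0, 4, 8, 11, 12, 13, 15]},
    {"feature": "sbp", "breaks": [110, 120, 130, 140, 150, 160], "points": [0, 1, 3, 6, 7, 8, 10]},
    {"feature": "bmi", "breaks": [22, 24, 30], "points": [0, 1, 3, 5]},
    {"feature": "wc", "breaks": [75, 80, 85, 90, 95], "points": [0, 3, 5, 7, 8, 10]},
    {"feature": "sex", "categories": {"0": 0, "1": 2}}
  ]
}
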