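{
  "name": "ADART-schema placeholder",
  "description": "PLACEHOLDER point values in the ADA diabetes risk test schema. The published point table is cited, not printed, in the source study; edit this file to use the official values. Only the screen-positive cutoff (5) is the published one. Feature coding: sex 1 = male; physical_activity 1 = active.",
  "cutoff": 5,
  "items": [
    {"feature": "age", "breaks": [40, 50, 60], "points": [0, 1, 2, 3]},
    {"feature": "sex", "categories": {"0": 0, "1": 1}},
    {"feature": "bmi", "breaks": [25, 30, 40], "points": [0, 1, 2, 3]},
    {"feature": "sbp", "breaks": [140], "points": [0, 1]},
    {"feature": "physical_activity", "categories": {"0": 1, "1": 0}}
  ]
}
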