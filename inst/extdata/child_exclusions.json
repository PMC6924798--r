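{
  "family": "child",
  "note": "Synthetic, plausibility-motivated exclusion rules. The study that motivates the default scheme removed 18 unrealistic vignettes from the 54 possible but did not publish the list; this illustrative rule set reproduces the cardinality (18 removed, 36 admissible) and is intended to be edited by users with domain knowledge.",
  "rules": [
    {
      "description": "a child not motivated to communicate through any methods and means would not have acquired use of AAC for a few communicative functions",
      "match": {"determination": "not_motivated", "communication_ability": "few_functions"}
    },
    {
      "description": "a child not motivated to communicate through any methods and means would not have acquired use of AAC for a range of communicative functions",
      "match": {"determination": "not_motivated", "communication_ability": "range_of_functions"}
    },
    {
      "description": "a child motivated only to communicate through methods other than symbol communication is unlikely to command a full range of AAC functions",
      "match": {"determination": "motivated_other_methods", "communication_ability": "range_of_functions"}
    }
  ]
}
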