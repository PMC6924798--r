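{
  "family": "system",
  "note": "Synthetic, plausibility-motivated exclusion rules. The study that motivates the default scheme removed 158 unrealistic systems from the 432 possible but did not publish the list; this illustrative rule set reproduces the cardinality (158 removed, 274 admissible) and is intended to be edited by users with domain knowledge.",
  "rules": [
    {
      "description": "semantic-syntactic organisation presupposes combining items into grammatical structures, implausible with at most 50 items",
      "match": {"size_of_vocabulary": "up_to_50", "vocabulary_organisation": "semantic_syntactic"}
    },
    {
      "description": "ideographic symbol systems rely on rule-based encoding over a large symbol inventory, implausible with at most 50 items",
      "match": {"size_of_vocabulary": "up_to_50", "graphical_representation": "ideographic"}
    },
    {
      "description": "staged-progression vocabulary sets simulate language development beyond a 50-item ceiling",
      "match": {"size_of_vocabulary": "up_to_50", "vocabulary_sets": "staged_progression"}
    },
    {
      "description": "a system outputting more than 1000 items cannot realistically be built from personal photographs",
      "match": {"size_of_vocabulary": "over_1000", "graphical_representation": "photos"}
    },
    {
      "description": "visual-scene organisation highlights areas of images; purely ideographic symbols do not form scenes",
      "match": {"vocabulary_organisation": "visual_scene", "graphical_representation": "ideographic"}
    },
    {
      "description": "visual scenes built from bare text with no preprovided vocabulary set give the child nothing scene-like to navigate",
      "match": {"vocabulary_organisation": "visual_scene", "graphical_representation": "text", "vocabulary_sets": "none"}
    },
    {
      "description": "over 1000 distinct familiar scenes with a fully consistent layout across all of them is unrealistic",
      "match": {"vocabulary_organisation": "visual_scene", "size_of_vocabulary": "over_1000", "layout_consistency": "all_aspects"}
    }
  ]
}
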