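# Default 43-item ordinal map: 10 items in 4 subscales + 33 standalone
# items = 37 modelled aspects. Items q21-q25 are reverse-coded
# (level 1 = worst) to exercise direction alignment.
missing_codes: [99]
items:
  - {id: q01, levels: 5, level1_best: true, subscale: near_activities}
  - {id: q02, levels: 5, level1_best: true, subscale: near_activities}
  - {id: q03, levels: 5, level1_best: true, subscale: near_activities}
  - {id: q04, levels: 5, level1_best: true, subscale: distance_activities}
  - {id: q05, levels: 5, level1_best: true, subscale: distance_activities}
  - {id: q06, levels: 5, level1_best: true, subscale: distance_activities}
  - {id: q07, levels: 5, level1_best: true, subscale: driving}
  - {id: q08, levels: 5, level1_best: true, subscale: driving}
  - {id: q09, levels: 5, level1_best: true, subscale: social_functioning}
  - {id: q10, levels: 5, level1_best: true, subscale: social_functioning}
  - {id: q11, levels: 6, level1_best: true}
  - {id: q12, levels: 6, level1_best: true}
  - {id: q13, levels: 6, level1_best: true}
  - {id: q14, levels: 6, level1_best: true}
  - {id: q15, levels: 6, level1_best: true}
  - {id: q16, levels: 6, level1_best: true}
  - {id: q17, levels: 6, level1_best: true}
  - {id: q18, levels: 6, level1_best: true}
  - {id: q19, levels: 6, level1_best: true}
  - {id: q20, levels: 6, level1_best: true}
  - {id: q21, levels: 5, level1_best: false}
  - {id: q22, levels: 5, level1_best: false}
  - {id: q23, levels: 5, level1_best: false}
  - {id: q24, levels: 5, level1_best: false}
  - {id: q25, levels: 5, level1_best: false}
  - {id: q26, levels: 5, level1_best: true}
  - {id: q27, levels: 5, level1_best: true}
  - {id: q28, levels: 5, level1_best: true}
  - {id: q29, levels: 5, level1_best: true}
  - {id: q30, levels: 5, level1_best: true}
  - {id: q31, levels: 5, level1_best: true}
  - {id: q32, levels: 5, level1_best: true}
  - {id: q33, levels: 5, level1_best: true}
  - {id: q34, levels: 5, level1_best: true}
  - {id: q35, levels: 5, level1_best: true}
  - {id: q36, levels: 5, level1_best: true}
  - {id: q37, levels: 5, level1_best: true}
  - {id: q38, levels: 5, level1_best: true}
  - {id: q39, levels: 5, level1_best: true}
  - {id: q40, levels: 5, level1_best: true}
  - {id: q41, levels: 5, level1_best: true}
  - {id: q42, levels: 5, level1_best: true}
  - {id: q43, levels: 5, level1_best: true}
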