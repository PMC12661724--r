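{
  "version": "ccmq-2016-default",
  "questions": [
    {
      "question_id": "Q01",
      "item_id": "I01",
      "constitution": "balanced",
      "polarity": "direct"
    },
    {
      "question_id": "Q02",
      "item_id": "I02",
      "constitution": "balanced",
      "polarity": "direct"
    },
    {
      "question_id": "Q03",
      "item_id": "I03",
      "constitution": "balanced",
      "polarity": "direct"
    },
    {
      "question_id": "Q04",
      "item_id": "I04",
      "constitution": "balanced",
      "polarity": "direct"
    },
    {
      "question_id": "Q05",
      "item_id": "I05",
      "constitution": "balanced",
      "polarity": "direct"
    },
    {
      "question_id": "Q06",
      "item_id": "I06",
      "constitution": "balanced",
      "polarity": "direct"
    },
    {
      "question_id": "Q07",
      "item_id": "I07",
      "constitution": "balanced",
      "polarity": "direct"
    },
    {
      "question_id": "Q08",
      "item_id": "I08",
      "constitution": "qi_deficiency",
      "polarity": "direct"
    },
    {
      "question_id": "Q09",
      "item_id": "I09",
      "constitution": "qi_deficiency",
      "polarity": "direct"
    },
    {
      "question_id": "Q10",
      "item_id": "I10",
      "constitution": "qi_deficiency",
      "polarity": "direct"
    },
    {
      "question_id": "Q11",
      "item_id": "I11",
      "constitution": "qi_deficiency",
      "polarity": "direct"
    },
    {
      "question_id": "Q12",
      "item_id": "I12",
      "constitution": "qi_deficiency",
      "polarity": "direct"
    },
    {
      "question_id": "Q13",
      "item_id": "I13",
      "constitution": "qi_deficiency",
      "polarity": "direct"
    },
    {
      "question_id": "Q14",
      "item_id": "I14",
      "constitution": "yin_deficiency",
      "polarity": "direct"
    },
    {
      "question_id": "Q15",
      "item_id": "I15",
      "constitution": "yin_deficiency",
      "polarity": "direct"
    },
    {
      "question_id": "Q16",
      "item_id": "I16",
      "constitution": "yin_deficiency",
      "polarity": "direct"
    },
    {
      "question_id": "Q17",
      "item_id": "I17",
      "constitution": "yin_deficiency",
      "polarity": "direct"
    },
    {
      "question_id": "Q18",
      "item_id": "I18",
      "constitution": "yin_deficiency",
      "polarity": "direct"
    },
    {
      "question_id": "Q19",
      "item_id": "I19",
      "constitution": "yin_deficiency",
      "polarity": "direct"
    },
    {
      "question_id": "Q20",
      "item_id": "I20",
      "constitution": "yang_deficiency",
      "polarity": "direct"
    },
    {
      "question_id": "Q21",
      "item_id": "I21",
      "constitution": "yang_deficiency",
      "polarity": "direct"
    },
    {
      "question_id": "Q22",
      "item_id": "I22",
      "constitution": "yang_deficiency",
      "polarity": "direct"
    },
    {
      "question_id": "Q23",
      "item_id": "I23",
      "constitution": "yang_deficiency",
      "polarity": "direct"
    },
    {
      "question_id": "Q24",
      "item_id": "I24",
      "constitution": "yang_deficiency",
      "polarity": "direct"
    },
    {
      "question_id": "Q25",
      "item_id": "I25",
      "constitution": "yang_deficiency",
      "polarity": "direct"
    },
    {
      "question_id": "Q26",
      "item_id": "I26",
      "constitution": "yang_deficiency",
      "polarity": "direct"
    },
    {
      "question_id": "Q27",
      "item_id": "I27",
      "constitution": "phlegm_dampness",
      "polarity": "direct"
    },
    {
      "question_id": "Q28",
      "item_id": "I28",
      "constitution": "phlegm_dampness",
      "polarity": "direct"
    },
    {
      "question_id": "Q29",
      "item_id": "I29",
      "constitution": "phlegm_dampness",
      "polarity": "direct"
    },
    {
      "question_id": "Q30",
      "item_id": "I30",
      "constitution": "phlegm_dampness",
      "polarity": "direct"
    },
    {
      "question_id": "Q31",
      "item_id": "I31",
      "constitution": "phlegm_dampness",
      "polarity": "direct"
    },
    {
      "question_id": "Q32",
      "item_id": "I32",
      "constitution": "damp_heat",
      "polarity": "direct"
    },
    {
      "question_id": "Q33",
      "item_id": "I33",
      "constitution": "damp_heat",
      "polarity": "direct"
    },
    {
      "question_id": "Q34",
      "item_id": "I34",
      "constitution": "damp_heat",
      "polarity": "direct"
    },
    {
      "question_id": "Q35",
      "item_id": "I35",
      "constitution": "damp_heat",
      "polarity": "direct"
    },
    {
      "question_id": "Q36",
      "item_id": "I36",
      "constitution": "damp_heat",
      "polarity": "direct"
    },
    {
      "question_id": "Q37",
      "item_id": "I37",
      "constitution": "damp_heat",
      "polarity": "direct"
    },
    {
      "question_id": "Q38",
      "item_id": "I38",
      "constitution": "blood_stasis",
      "polarity": "direct"
    },
    {
      "question_id": "Q39",
      "item_id": "I39",
      "constitution": "blood_stasis",
      "polarity": "direct"
    },
    {
      "question_id": "Q40",
      "item_id": "I40",
      "constitution": "blood_stasis",
      "polarity": "direct"
    },
    {
      "question_id": "Q41",
      "item_id": "I41",
      "constitution": "blood_stasis",
      "polarity": "direct"
    },
    {
      "question_id": "Q42",
      "item_id": "I42",
      "constitution": "blood_stasis",
      "polarity": "direct"
    },
    {
      "question_id": "Q43",
      "item_id": "I43",
      "constitution": "blood_stasis",
      "polarity": "direct"
    },
    {
      "question_id": "Q44",
      "item_id": "I44",
      "constitution": "blood_stasis",
      "polarity": "direct"
    },
    {
      "question_id": "Q45",
      "item_id": "I45",
      "constitution": "qi_stagnation",
      "polarity": "direct"
    },
    {
      "question_id": "Q46",
      "item_id": "I46",
      "constitution": "qi_stagnation",
      "polarity": "direct"
    },
    {
      "question_id": "Q47",
      "item_id": "I47",
      "constitution": "qi_stagnation",
      "polarity": "direct"
    },
    {
      "question_id": "Q48",
      "item_id": "I48",
      "constitution": "qi_stagnation",
      "polarity": "direct"
    },
    {
      "question_id": "Q49",
      "item_id": "I49",
      "constitution": "qi_stagnation",
      "polarity": "direct"
    },
    {
      "question_id": "Q50",
      "item_id": "I50",
      "constitution": "qi_stagnation",
      "polarity": "direct"
    },
    {
      "question_id": "Q51",
      "item_id": "I51",
      "constitution": "qi_stagnation",
      "polarity": "direct"
    },
    {
      "question_id": "Q52",
      "item_id": "I52",
      "constitution": "inherited_special",
      "polarity": "direct"
    },
    {
      "question_id": "Q53",
      "item_id": "I53",
      "constitution": "inherited_special",
      "polarity": "direct"
    },
    {
      "question_id": "Q54",
      "item_id": "I54",
      "constitution": "inherited_special",
      "polarity": "direct"
    },
    {
      "question_id": "Q55",
      "item_id": "I54",
      "constitution": "inherited_special",
      "polarity": "direct"
    },
    {
      "question_id": "Q56",
      "item_id": "I54",
      "constitution": "inherited_special",
      "polarity": "direct"
    },
    {
      "question_id": "Q57",
      "item_id": "I54",
      "constitution": "inherited_special",
      "polarity": "direct"
    }
  ]
}
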