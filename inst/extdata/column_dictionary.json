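{
  "description": "Column dictionary for PVQ cohort CSV files (UTF-8, one row per patient)",
  "patient_id": "opaque string identifier",
  "items": [
    {
      "column": "oq_3",
      "instrument": "oq",
      "item": 3,
      "min": 0,
      "max": 4
    },
    {
      "column": "oq_8",
      "instrument": "oq",
      "item": 8,
      "min": 0,
      "max": 4
    },
    {
      "column": "oq_13",
      "instrument": "oq",
      "item": 13,
      "min": 0,
      "max": 4
    },
    {
      "column": "oq_24",
      "instrument": "oq",
      "item": 24,
      "min": 0,
      "max": 4
    },
    {
      "column": "oq_31",
      "instrument": "oq",
      "item": 31,
      "min": 0,
      "max": 4
    },
    {
      "column": "deq_3",
      "instrument": "deq",
      "item": 3,
      "min": 1,
      "max": 7
    },
    {
      "column": "deq_16",
      "instrument": "deq",
      "item": 16,
      "min": 1,
      "max": 7
    },
    {
      "column": "deq_19",
      "instrument": "deq",
      "item": 19,
      "min": 1,
      "max": 7
    },
    {
      "column": "deq_48",
      "instrument": "deq",
      "item": 48,
      "min": 1,
      "max": 7
    },
    {
      "column": "deq_56",
      "instrument": "deq",
      "item": 56,
      "min": 1,
      "max": 7
    },
    {
      "column": "deq_62",
      "instrument": "deq",
      "item": 62,
      "min": 1,
      "max": 7
    },
    {
      "column": "rfl_2",
      "instrument": "rfl",
      "item": 2,
      "min": 1,
      "max": 6
    },
    {
      "column": "rfl_5",
      "instrument": "rfl",
      "item": 5,
      "min": 1,
      "max": 6
    },
    {
      "column": "rfl_10",
      "instrument": "rfl",
      "item": 10,
      "min": 1,
      "max": 6
    },
    {
      "column": "rfl_12",
      "instrument": "rfl",
      "item": 12,
      "min": 1,
      "max": 6
    },
    {
      "column": "rfl_14",
      "instrument": "rfl",
      "item": 14,
      "min": 1,
      "max": 6
    },
    {
      "column": "rfl_17",
      "instrument": "rfl",
      "item": 17,
      "min": 1,
      "max": 6
    },
    {
      "column": "rfl_19",
      "instrument": "rfl",
      "item": 19,
      "min": 1,
      "max": 6
    },
    {
      "column": "rfl_20",
      "instrument": "rfl",
      "item": 20,
      "min": 1,
      "max": 6
    },
    {
      "column": "rfl_22",
      "instrument": "rfl",
      "item": 22,
      "min": 1,
      "max": 6
    },
    {
      "column": "rfl_24",
      "instrument": "rfl",
      "item": 24,
      "min": 1,
      "max": 6
    },
    {
      "column": "rfl_25",
      "instrument": "rfl",
      "item": 25,
      "min": 1,
      "max": 6
    },
    {
      "column": "rfl_40",
      "instrument": "rfl",
      "item": 40,
      "min": 1,
      "max": 6
    },
    {
      "column": "rfl_45",
      "instrument": "rfl",
      "item": 45,
      "min": 1,
      "max": 6
    },
    {
      "column": "rfl_50",
      "instrument": "rfl",
      "item": 50,
      "min": 1,
      "max": 6
    }
  ],
  "demographics": {
    "diagnosis": ["mild_depressive", "moderate_depressive", "major_depressive", "bipolar", "adjustment", "anxiety", "mixed_episode", "dysthymia", "other"],
    "children": ["0", "1", "2", "3", "4", "5+"],
    "gender": ["woman", "man", "other"],
    "age_band": ["18-28", "28-38", "38-48", "48-58", "58-68", "68-78", ">78"],
    "schooling": ["basic", "secondary", "technical", "university"],
    "cohabitation": ["alone", "friends", "couple", "family"],
    "marital_status": ["single", "married", "separated", "widow", "free_union"],
    "occupation": ["employed", "student", "unemployed", "housewife", "retired/not_working"]
  },
  "age_band_codings": {
    "table7": ["18-28", "28-38", "38-48", "48-58", "58-68", "68-78", ">78"],
    "table3": ["14-19", "20-29", "30-39", "40-49", "50-59", "60+"]
  },
  "sb_status": ["none", "ideation", "attempt_low_severity", "attempt_high_severity"]
}
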