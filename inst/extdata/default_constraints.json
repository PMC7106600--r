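{
  "whitelist": [],
  "blacklist": [
    {
      "from": "oq_level",
      "to": "diagnosis"
    },
    {
      "from": "oq_level",
      "to": "children"
    },
    {
      "from": "oq_level",
      "to": "gender"
    },
    {
      "from": "oq_level",
      "to": "age_band"
    },
    {
      "from": "oq_level",
      "to": "schooling"
    },
    {
      "from": "oq_level",
      "to": "cohabitation"
    },
    {
      "from": "oq_level",
      "to": "marital_status"
    },
    {
      "from": "oq_level",
      "to": "occupation"
    },
    {
      "from": "oq8",
      "to": "diagnosis"
    },
    {
      "from": "oq8",
      "to": "children"
    },
    {
      "from": "oq8",
      "to": "gender"
    },
    {
      "from": "oq8",
      "to": "age_band"
    },
    {
      "from": "oq8",
      "to": "schooling"
    },
    {
      "from": "oq8",
      "to": "cohabitation"
    },
    {
      "from": "oq8",
      "to": "marital_status"
    },
    {
      "from": "oq8",
      "to": "occupation"
    },
    {
      "from": "rfl_level",
      "to": "diagnosis"
    },
    {
      "from": "rfl_level",
      "to": "children"
    },
    {
      "from": "rfl_level",
      "to": "gender"
    },
    {
      "from": "rfl_level",
      "to": "age_band"
    },
    {
      "from": "rfl_level",
      "to": "schooling"
    },
    {
      "from": "rfl_level",
      "to": "cohabitation"
    },
    {
      "from": "rfl_level",
      "to": "marital_status"
    },
    {
      "from": "rfl_level",
      "to": "occupation"
    },
    {
      "from": "rfl25",
      "to": "diagnosis"
    },
    {
      "from": "rfl25",
      "to": "children"
    },
    {
      "from": "rfl25",
      "to": "gender"
    },
    {
      "from": "rfl25",
      "to": "age_band"
    },
    {
      "from": "rfl25",
      "to": "schooling"
    },
    {
      "from": "rfl25",
      "to": "cohabitation"
    },
    {
      "from": "rfl25",
      "to": "marital_status"
    },
    {
      "from": "rfl25",
      "to": "occupation"
    },
    {
      "from": "deq_quadrant",
      "to": "diagnosis"
    },
    {
      "from": "deq_quadrant",
      "to": "children"
    },
    {
      "from": "deq_quadrant",
      "to": "gender"
    },
    {
      "from": "deq_quadrant",
      "to": "age_band"
    },
    {
      "from": "deq_quadrant",
      "to": "schooling"
    },
    {
      "from": "deq_quadrant",
      "to": "cohabitation"
    },
    {
      "from": "deq_quadrant",
      "to": "marital_status"
    },
    {
      "from": "deq_quadrant",
      "to": "occupation"
    },
    {
      "from": "diagnosis",
      "to": "children"
    },
    {
      "from": "diagnosis",
      "to": "gender"
    },
    {
      "from": "diagnosis",
      "to": "age_band"
    },
    {
      "from": "diagnosis",
      "to": "schooling"
    },
    {
      "from": "diagnosis",
      "to": "cohabitation"
    },
    {
      "from": "diagnosis",
      "to": "marital_status"
    },
    {
      "from": "diagnosis",
      "to": "occupation"
    },
    {
      "from": "children",
      "to": "diagnosis"
    },
    {
      "from": "children",
      "to": "gender"
    },
    {
      "from": "children",
      "to": "age_band"
    },
    {
      "from": "children",
      "to": "schooling"
    },
    {
      "from": "children",
      "to": "cohabitation"
    },
    {
      "from": "children",
      "to": "marital_status"
    },
    {
      "from": "children",
      "to": "occupation"
    },
    {
      "from": "gender",
      "to": "diagnosis"
    },
    {
      "from": "gender",
      "to": "children"
    },
    {
      "from": "gender",
      "to": "age_band"
    },
    {
      "from": "gender",
      "to": "schooling"
    },
    {
      "from": "gender",
      "to": "cohabitation"
    },
    {
      "from": "gender",
      "to": "marital_status"
    },
    {
      "from": "gender",
      "to": "occupation"
    },
    {
      "from": "age_band",
      "to": "diagnosis"
    },
    {
      "from": "age_band",
      "to": "children"
    },
    {
      "from": "age_band",
      "to": "gender"
    },
    {
      "from": "age_band",
      "to": "schooling"
    },
    {
      "from": "age_band",
      "to": "cohabitation"
    },
    {
      "from": "age_band",
      "to": "marital_status"
    },
    {
      "from": "age_band",
      "to": "occupation"
    },
    {
      "from": "schooling",
      "to": "diagnosis"
    },
    {
      "from": "schooling",
      "to": "children"
    },
    {
      "from": "schooling",
      "to": "gender"
    },
    {
      "from": "schooling",
      "to": "age_band"
    },
    {
      "from": "schooling",
      "to": "cohabitation"
    },
    {
      "from": "schooling",
      "to": "marital_status"
    },
    {
      "from": "schooling",
      "to": "occupation"
    },
    {
      "from": "cohabitation",
      "to": "diagnosis"
    },
    {
      "from": "cohabitation",
      "to": "children"
    },
    {
      "from": "cohabitation",
      "to": "gender"
    },
    {
      "from": "cohabitation",
      "to": "age_band"
    },
    {
      "from": "cohabitation",
      "to": "schooling"
    },
    {
      "from": "cohabitation",
      "to": "marital_status"
    },
    {
      "from": "cohabitation",
      "to": "occupation"
    },
    {
      "from": "marital_status",
      "to": "diagnosis"
    },
    {
      "from": "marital_status",
      "to": "children"
    },
    {
      "from": "marital_status",
      "to": "gender"
    },
    {
      "from": "marital_status",
      "to": "age_band"
    },
    {
      "from": "marital_status",
      "to": "schooling"
    },
    {
      "from": "marital_status",
      "to": "cohabitation"
    },
    {
      "from": "marital_status",
      "to": "occupation"
    },
    {
      "from": "occupation",
      "to": "diagnosis"
    },
    {
      "from": "occupation",
      "to": "children"
    },
    {
      "from": "occupation",
      "to": "gender"
    },
    {
      "from": "occupation",
      "to": "age_band"
    },
    {
      "from": "occupation",
      "to": "schooling"
    },
    {
      "from": "occupation",
      "to": "cohabitation"
    },
    {
      "from": "occupation",
      "to": "marital_status"
    },
    {
      "from": "sb_group",
      "to": "diagnosis"
    },
    {
      "from": "sb_group",
      "to": "children"
    },
    {
      "from": "sb_group",
      "to": "gender"
    },
    {
      "from": "sb_group",
      "to": "age_band"
    },
    {
      "from": "sb_group",
      "to": "schooling"
    },
    {
      "from": "sb_group",
      "to": "cohabitation"
    },
    {
      "from": "sb_group",
      "to": "marital_status"
    },
    {
      "from": "sb_group",
      "to": "occupation"
    },
    {
      "from": "sb_group",
      "to": "oq_level"
    },
    {
      "from": "sb_group",
      "to": "oq8"
    },
    {
      "from": "sb_group",
      "to": "rfl_level"
    },
    {
      "from": "sb_group",
      "to": "rfl25"
    },
    {
      "from": "sb_group",
      "to": "deq_quadrant"
    },
    {
      "from": "sb_group",
      "to": "diagnosis"
    },
    {
      "from": "sb_group",
      "to": "children"
    },
    {
      "from": "sb_group",
      "to": "gender"
    },
    {
      "from": "sb_group",
      "to": "age_band"
    },
    {
      "from": "sb_group",
      "to": "schooling"
    },
    {
      "from": "sb_group",
      "to": "cohabitation"
    },
    {
      "from": "sb_group",
      "to": "marital_status"
    },
    {
      "from": "sb_group",
      "to": "occupation"
    }
  ]
}
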