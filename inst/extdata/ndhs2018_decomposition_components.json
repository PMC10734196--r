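{
  "description": "Published overall and detailed threefold decomposition estimates for the rural-urban overweight/obesity gap, 2018 Nigeria DHS women's sample (n = 13,339). Used as worked-example inputs for percent-contribution arithmetic; the package cannot refit the restricted microdata.",
  "mean_prediction": {"urban": 0.355, "rural": 0.211},
  "components": {"D": 0.144, "E": 0.123, "C": 0.018, "I": 0.003},
  "detail_endowment_parts": {
    "wealth_poor": 0.035,
    "wealth_middle": -0.0003,
    "wealth_rich": 0.035,
    "education_none": 0.023,
    "media_not_exposed": 0.007,
    "media_exposed": 0.007,
    "contraceptive_user": 0.003
  }
}
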