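{
 "raw_ratio_ors": 1.25,
 "raw_ratio_itn": 0.8333333333333334,
 "applied_ratio_itn": 1.0,
 "applied_ratio_zinc": 1.25,
 "target_ors": 0.5,
 "target_zinc": 0.25,
 "deaths_baseline_total": 5000.0,
 "deaths_scenario_diarrhea_full": 2758.1568341622365,
 "lives_saved_full": 241.84316583776368,
 "lives_saved_limited": 206.6326530612245,
 "attribution_ors_full": 205.34308172194045,
 "attribution_zinc_full": 36.50008411582321,
 "u5mr_change_full": -2.418431658377637
}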