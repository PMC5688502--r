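country_id,intervention_id,national,q1,q2,q3,q4,q5
wex,cpr,0.30,0.22,0.26,0.30,0.34,0.40
wex,ors,0.40,0.30,0.35,0.40,0.45,0.50
wex,zinc,0.20,,,,,
wex,itn,0.60,0.70,0.65,0.60,0.55,0.50
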