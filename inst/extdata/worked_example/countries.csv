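country_id,survey_year,live_births,nmr,post_nmr,tfr,ncause_other,pcause_diarrhea,pcause_malaria
wex,2010,100000,0,50,2.0,1.0,0.6,0.4
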