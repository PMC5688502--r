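{
  "cpr_effectiveness": 0.9,
  "fertility_gate": 2.33,
  "interventions": [
    {"intervention_id": "cpr", "name": "Contraceptive prevalence rate (CPR)", "channel": "direct", "parent_id": null, "source_id": null, "backup_id": null, "is_parent": false, "is_cpr": true, "group": "fertility"},
    {"intervention_id": "ors", "name": "Oral rehydration solution (ORS)", "channel": "direct", "parent_id": null, "source_id": null, "backup_id": null, "is_parent": false, "is_cpr": false, "group": "case_management"},
    {"intervention_id": "zinc", "name": "Zinc for treatment of diarrhea", "channel": "proxied", "parent_id": null, "source_id": "ors", "backup_id": null, "is_parent": false, "is_cpr": false, "group": "case_management"},
    {"intervention_id": "itn", "name": "Insecticide treated bednet (ITN)", "channel": "direct", "parent_id": null, "source_id": null, "backup_id": null, "is_parent": false, "is_cpr": false, "group": "preventive"}
  ],
  "effects": [
    {"intervention_id": "ors", "age_band": "postneonatal", "cause": "diarrhea", "effectiveness": 0.6, "affected_fraction": 0.9},
    {"intervention_id": "zinc", "age_band": "postneonatal", "cause": "diarrhea", "effectiveness": 0.3, "affected_fraction": 0.8},
    {"intervention_id": "itn", "age_band": "postneonatal", "cause": "malaria", "effectiveness": 0.5, "affected_fraction": 0.8}
  ]
}
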