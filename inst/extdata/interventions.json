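{
  "counselling": {
    "label": "Dietary counselling (current practice)",
    "kind": "counselling",
    "per_hour_effect": 7.6,
    "per_hour_sd": 0.8,
    "hours_mean": 4600,
    "hours_sd": 920,
    "phase_years": 1,
    "cost_onetime": 0,
    "cost_annual": 575000,
    "cost_distribution": "normal",
    "cost_sd_rel": 0.10
  },
  "endorsement_label": {
    "label": "Endorsement label programme (current practice)",
    "kind": "immediate",
    "effect_mean": 1.7,
    "effect_sd_rel": 0.20,
    "phase_years": 1,
    "cost_onetime": 0,
    "cost_annual": 621000,
    "cost_distribution": "gamma",
    "cost_sd": 62100
  },
  "mandatory_3g": {
    "label": "Mandatory 25% sodium reduction: bread, processed meats, sauces",
    "kind": "immediate",
    "effect_mean": 12.9,
    "effect_sd_rel": 0.10,
    "phase_years": 1,
    "cost_onetime": 3680000,
    "cost_annual": 0,
    "cost_distribution": "gamma",
    "cost_sd_rel": 0.25
  },
  "mandatory_all": {
    "label": "Mandatory 25% sodium reduction: all processed foods",
    "kind": "immediate",
    "effect_mean": 22.8,
    "effect_sd_rel": 0.10,
    "phase_years": 1,
    "cost_onetime": 3680000,
    "cost_annual": 0,
    "cost_distribution": "gamma",
    "cost_sd_rel": 0.25
  },
  "uk_package": {
    "label": "UK package (media campaign + reformulation + labelling)",
    "kind": "ramp",
    "effect_mean": 22.7,
    "effect_sd_rel": 0.10,
    "phase_years": 7,
    "cost_onetime": 12100000,
    "cost_annual": 0,
    "cost_distribution": "gamma",
    "cost_sd_rel": 0.10
  },
  "uk_media": {
    "label": "UK mass media campaign only",
    "kind": "media",
    "package_effect": 22.7,
    "campaign_share": 0.30,
    "share_range": [0.15, 0.45],
    "effect_sd_rel": 0.30,
    "phase_years": 7,
    "cost_onetime": 10400000,
    "cost_annual": 0,
    "cost_distribution": "gamma",
    "cost_sd_rel": 0.10
  },
  "salt_tax": {
    "label": "Salt excise tax to a 2300 mg/d intake target",
    "kind": "tax",
    "target_mg": 2300,
    "elasticity": -0.1,
    "annual_cap": 0.20,
    "horizon_years": 10,
    "effect_sd_rel": 0.10,
    "phase_years": 10,
    "cost_onetime": 3680000,
    "cost_annual": 0,
    "cost_distribution": "gamma",
    "cost_sd_rel": 0.25
  },
  "sinking_lid": {
    "label": "Sinking lid on food-grade salt supply to a 2300 mg/d target",
    "kind": "sinking_lid",
    "target_mg": 2300,
    "years_to_target": 6,
    "effect_sd_rel": 0.10,
    "phase_years": 6,
    "cost_onetime": 3680000,
    "cost_annual": 0,
    "cost_distribution": "gamma",
    "cost_sd_rel": 0.25
  }
}
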