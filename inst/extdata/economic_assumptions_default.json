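{
  "solvent_price_alt": 5,
  "solvent_price_ref": 0.9,
  "solvent_consumption": 0.75,
  "extra_steam": 37,
  "steam_price": 30,
  "extra_oil_gross": 10,
  "oil_recovery_value_fraction": 0.60,
  "oil_price": 900,
  "cake_price": 350,
  "capacity_gain_fraction": 0.05,
  "fixed_cost_reduction": 0.8
}
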