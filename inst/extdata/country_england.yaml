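country: england
wage_per_hour: 17.5
informal_care_price_per_hour: 15.0
inflation_index: 1.0
discount_rate: 0.035
unit_costs_csv: unit_costs_england.csv
school_cost_per_year:
  intervention: 7000
  control: 7000
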