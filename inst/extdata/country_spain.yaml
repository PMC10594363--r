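country: spain
wage_per_hour: 13.0
informal_care_price_per_hour: 11.5
inflation_index: 1.0
discount_rate: 0.035
unit_costs_csv: unit_costs_spain.csv
school_cost_per_year:
  intervention: 5460
  control: 5460
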