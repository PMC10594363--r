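country: italy
wage_per_hour: 14.0
informal_care_price_per_hour: 12.5
inflation_index: 1.0
discount_rate: 0.035
unit_costs_csv: unit_costs_italy.csv
school_cost_per_year:
  intervention: 5740
  control: 5740
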