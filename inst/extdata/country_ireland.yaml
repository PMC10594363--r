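country: ireland
wage_per_hour: 19.0
informal_care_price_per_hour: 16.0
inflation_index: 1.0
discount_rate: 0.035
unit_costs_csv: unit_costs_ireland.csv
school_cost_per_year:
  intervention: 7420
  control: 7420
out_of_pocket:
  pact_mean: 1696
  table: oop_ireland_synthetic.csv
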