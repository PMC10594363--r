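item,mean_cost
living_costs,2350
care_and_assistance,2900
education,1450
healthcare,1050
travel,680
training_support,594
autism_assistance_dog,575
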