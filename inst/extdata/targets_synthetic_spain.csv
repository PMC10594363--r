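arm,category,mean_cost
intervention,pact_delivery,4834.44
intervention,speech_language_therapy,468
intervention,community_health_social,351
intervention,hospital_health,314.34
intervention,education_childcare,6240
intervention,social_care,1170
intervention,parental_productivity,7800
intervention,parental_informal_care,53459.64
control,pact_delivery,0
control,speech_language_therapy,608.4
control,community_health_social,405.6
control,hospital_health,329.94
control,education_childcare,7176
control,social_care,1340.04
control,parental_productivity,8580
control,parental_informal_care,59020.26
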