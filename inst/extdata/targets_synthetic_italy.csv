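arm,category,mean_cost
intervention,pact_delivery,5082.36
intervention,speech_language_therapy,492
intervention,community_health_social,369
intervention,hospital_health,330.46
intervention,education_childcare,6560
intervention,social_care,1230
intervention,parental_productivity,8200
intervention,parental_informal_care,56201.16
control,pact_delivery,0
control,speech_language_therapy,639.6
control,community_health_social,426.4
control,hospital_health,346.86
control,education_childcare,7544
control,social_care,1408.76
control,parental_productivity,9020
control,parental_informal_care,62046.94
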