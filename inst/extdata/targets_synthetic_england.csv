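arm,category,mean_cost
intervention,pact_delivery,6198
intervention,speech_language_therapy,600
intervention,community_health_social,450
intervention,hospital_health,403
intervention,education_childcare,8000
intervention,social_care,1500
intervention,parental_productivity,10000
intervention,parental_informal_care,68538
control,pact_delivery,0
control,speech_language_therapy,780
control,community_health_social,520
control,hospital_health,423
control,education_childcare,9200
control,social_care,1718
control,parental_productivity,11000
control,parental_informal_care,75667
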