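arm,category,mean_cost
intervention,pact_delivery,6569.88
intervention,speech_language_therapy,636
intervention,community_health_social,477
intervention,hospital_health,427.18
intervention,education_childcare,8480
intervention,social_care,1590
intervention,parental_productivity,10600
intervention,parental_informal_care,72650.28
control,pact_delivery,0
control,speech_language_therapy,826.8
control,community_health_social,551.2
control,hospital_health,448.38
control,education_childcare,9752
control,social_care,1821.08
control,parental_productivity,11660
control,parental_informal_care,80207.02
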