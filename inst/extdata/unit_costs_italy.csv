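item_id,category,euro_per_unit
pact_delivery,pact_delivery,5082.36
slt_session,speech_language_therapy,49.2
gp_visit,community_health_social,31.98
paediatrician_visit,community_health_social,98.4
social_worker_visit,social_care,69.7
hospital_outpatient,hospital_health,110.7
hospital_inpatient_day,hospital_health,369
nursery_day,education_childcare,45.1
time_off_work,parental_productivity,NA
informal_care,parental_informal_care,NA
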