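item_id,category,euro_per_unit
pact_delivery,pact_delivery,6198
slt_session,speech_language_therapy,60
gp_visit,community_health_social,39
paediatrician_visit,community_health_social,120
social_worker_visit,social_care,85
hospital_outpatient,hospital_health,135
hospital_inpatient_day,hospital_health,450
nursery_day,education_childcare,55
time_off_work,parental_productivity,NA
informal_care,parental_informal_care,NA
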