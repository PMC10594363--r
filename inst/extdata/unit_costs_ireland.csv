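item_id,category,euro_per_unit
pact_delivery,pact_delivery,6569.88
slt_session,speech_language_therapy,63.6
gp_visit,community_health_social,41.34
paediatrician_visit,community_health_social,127.2
social_worker_visit,social_care,90.1
hospital_outpatient,hospital_health,143.1
hospital_inpatient_day,hospital_health,477
nursery_day,education_childcare,58.3
time_off_work,parental_productivity,NA
informal_care,parental_informal_care,NA
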