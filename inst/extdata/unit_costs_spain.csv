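item_id,category,euro_per_unit
pact_delivery,pact_delivery,4834.44
slt_session,speech_language_therapy,46.8
gp_visit,community_health_social,30.42
paediatrician_visit,community_health_social,93.6
social_worker_visit,social_care,66.3
hospital_outpatient,hospital_health,105.3
hospital_inpatient_day,hospital_health,351
nursery_day,education_childcare,42.9
time_off_work,parental_productivity,NA
informal_care,parental_informal_care,NA
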