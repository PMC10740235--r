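category,item,unit,unit_cost_eur
inpatient,psychiatric_inpatient_day,day,450
inpatient,pediatric_inpatient_day,day,520
outpatient,psychiatrist_contact,contact,95
outpatient,psychotherapist_session,session,92
outpatient,pediatrician_contact,contact,45
institutional_welfare,residential_care_day,day,160
institutional_welfare,day_group_care_day,day,85
ambulant_welfare,family_support_hour,hour,55
ambulant_welfare,educational_assistance_hour,hour,48
medication,antidepressant_pack,pack,35
medication,stimulant_pack,pack,42
school_based,school_social_worker_hour,hour,40
school_based,school_psychologist_hour,hour,60
school_based,integration_assistant_hour,hour,32
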