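"set_name","concept_id","concept_name"
"rpl_diagnosis","OMOP:RPL_DX","OMOP:RPL_DX"
"pregnancy_loss","OMOP:LOSS_MISCARRIAGE","OMOP:LOSS_MISCARRIAGE"
"pregnancy_loss","OMOP:LOSS_FETAL_DEATH","OMOP:LOSS_FETAL_DEATH"
"pregnancy_loss","OMOP:LOSS_STILLBIRTH","OMOP:LOSS_STILLBIRTH"
"history_of_loss","OMOP:HX_PREGNANCY_LOSS","OMOP:HX_PREGNANCY_LOSS"
"live_birth","OMOP:BIRTH_FULLTERM","OMOP:BIRTH_FULLTERM"
"live_birth","OMOP:BIRTH_NORMAL_DELIVERY","OMOP:BIRTH_NORMAL_DELIVERY"
"control_exclusion","OMOP:EXTRAUTERINE_PREGNANCY","OMOP:EXTRAUTERINE_PREGNANCY"
"control_exclusion","OMOP:LOSS_FETAL_DEATH","OMOP:LOSS_FETAL_DEATH"
"control_exclusion","OMOP:LOSS_MISCARRIAGE","OMOP:LOSS_MISCARRIAGE"
"control_exclusion","OMOP:LOSS_STILLBIRTH","OMOP:LOSS_STILLBIRTH"
"control_exclusion","OMOP:MOLAR_PREGNANCY","OMOP:MOLAR_PREGNANCY"
"control_exclusion","OMOP:MULTI_GESTATION_LOSS","OMOP:MULTI_GESTATION_LOSS"
"control_exclusion","OMOP:PRETERM_BIRTH","OMOP:PRETERM_BIRTH"
"control_exclusion","OMOP:PRETERM_LABOR","OMOP:PRETERM_LABOR"
"control_exclusion","OMOP:PROM","OMOP:PROM"
"incident_pregnancy","OMOP:BIRTH_FULLTERM","OMOP:BIRTH_FULLTERM"
"incident_pregnancy","OMOP:BIRTH_NORMAL_DELIVERY","OMOP:BIRTH_NORMAL_DELIVERY"
"incident_pregnancy","OMOP:LOSS_FETAL_DEATH","OMOP:LOSS_FETAL_DEATH"
"incident_pregnancy","OMOP:LOSS_MISCARRIAGE","OMOP:LOSS_MISCARRIAGE"
"incident_pregnancy","OMOP:LOSS_STILLBIRTH","OMOP:LOSS_STILLBIRTH"
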