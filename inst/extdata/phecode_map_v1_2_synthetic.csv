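"icd_code","icd_flavor","phecode","phecode_string","category"
"N92.6","10","626.8","Irregular menstrual cycle/bleeding","genitourinary"
"N91.2","10","626.1","Absent or infrequent menstruation","genitourinary"
"N92.0","10","626.2","Excessive or frequent menstruation","genitourinary"
"N97.9","10","628","Infertility, female","genitourinary"
"N80.9","10","615","Endometriosis","genitourinary"
"E28.2","10","256.4","Polycystic ovaries","endocrine/metabolic"
"E28.8","10","256","Ovarian dysfunction","endocrine/metabolic"
"D68.59","10","286.81","Primary hypercoagulable state","hematopoietic"
"E88.81","10","277.7","Dysmetabolic syndrome X","endocrine/metabolic"
"O20.0","10","640","Hemorrhage in early pregnancy","pregnancy complications"
"O80","10","650","Normal delivery","pregnancy complications"
"O14.90","10","642.1","Preeclampsia and eclampsia","pregnancy complications"
"O99.01","10","648.8","Anemia during pregnancy","pregnancy complications"
"F41.9","10","300.1","Anxiety disorder","mental disorders"
"E11.9","10","250.2","Type 2 diabetes","endocrine/metabolic"
"R01.9","10","901.0","Null filler diagnosis 1","symptoms"
"R02.9","10","902.0","Null filler diagnosis 2","symptoms"
"R03.9","10","903.0","Null filler diagnosis 3","symptoms"
"R04.9","10","904.0","Null filler diagnosis 4","symptoms"
"R05.9","10","905.0","Null filler diagnosis 5","symptoms"
"R06.9","10","906.0","Null filler diagnosis 6","symptoms"
"R07.9","10","907.0","Null filler diagnosis 7","symptoms"
"R08.9","10","908.0","Null filler diagnosis 8","symptoms"
"R09.9","10","909.0","Null filler diagnosis 9","symptoms"
"R10.9","10","910.0","Null filler diagnosis 10","symptoms"
"Z00.00","10","1010","Other tests","other tests"
"649.51","9","634.1","Miscarriage; stillbirth","pregnancy complications"
"634.91","9","634","Miscarriage; stillbirth","pregnancy complications"
"V23.9","9","649","Other high-risk pregnancy","pregnancy complications"
"E11.9","10","250.2","Type 2 diabetes","endocrine/metabolic"
"250.00","9","250.2","Type 2 diabetes","endocrine/metabolic"
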