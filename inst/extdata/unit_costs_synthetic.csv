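category,unit,euro_per_unit,price_year,mental_health,payer
inpatient_rehabilitation,day,350,2020,FALSE,TRUE
outpatient_physician,contact,45,2020,TRUE,TRUE
outpatient_nonphysician,contact,35,2020,FALSE,TRUE
medical_aids,item,60,2020,FALSE,TRUE
medical_counseling,contact,50,2020,TRUE,TRUE
psychotherapy,session,90,2020,TRUE,TRUE
transportation,trip,15,2020,FALSE,TRUE
medication,pack,40,2020,TRUE,TRUE
nursing_care,care_hour,NA,2020,FALSE,TRUE
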