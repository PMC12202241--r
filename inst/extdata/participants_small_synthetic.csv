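# trialcea_cohort schema_version=1.0 recall_months_t0=6 recall_months_t1=4
participant_id,arm,age_years,gender_identity,eq5d_profile_t0,eq5d_profile_t1,eq5d_index_t0,eq5d_index_t1,eq_vas_t0,eq_vas_t1,gsi_t0,gsi_t1,work_days_absent_t1,work_days_present_t1,work_performance_t1,intervention_cost_t1,flag_intention_to_treat,flag_analysis_population,flag_per_protocol,ru_t0_inpatient_rehabilitation,ru_t0_outpatient_physician,ru_t0_outpatient_nonphysician,ru_t0_medical_aids,ru_t0_medical_counseling,ru_t0_psychotherapy,ru_t0_transportation,ru_t0_medication,ru_t0_nursing_care,ru_t1_inpatient_rehabilitation,ru_t1_outpatient_physician,ru_t1_outpatient_nonphysician,ru_t1_medical_aids,ru_t1_medical_counseling,ru_t1_psychotherapy,ru_t1_transportation,ru_t1_medication,ru_t1_nursing_care
P0001,IG,18,trans_feminine,,,0.8204482048600767,0.665701435896339,65.61793773562093,71.40462784208547,27.65655201439828,21.963005106832338,2.307653279274332,27.621332543679088,9.472389805992837,596.9607784150345,TRUE,TRUE,TRUE,0,28.93276749479081,0,0,12.969283669306002,0,15.11641184746921,0,0,0,0,1.4728211019497814,0,22.67193876652051,0,0,0.5428529803340947,0
P0002,IG,25.102139334403756,nonbinary,,,1,0.9242424696855501,72.70201904407732,90.68822008437854,28.999244161618847,19.870622466452712,1.1430051284721539,24.041057240948096,10,713.7112808647204,TRUE,TRUE,TRUE,0,50.77359763075035,0,13.138685628651933,0,0,5.784254826465514,9.611997459986656,41.72912260562274,0,6.128542762098366,2.0647607099023055,0.674835541149463,9.547392812227411,0,0,1.524635699512958,174.05345442194212
P0003,CG,45.24094376808115,trans_masculine,,,1,0.7345613420688126,69.1915300629611,69.8047826188803,27.21059936226349,26.73532369745479,1.0609785197313055,12.658465365048933,8.995435334180145,0,TRUE,TRUE,TRUE,0,0,3.6044453535631424,0,0,0,4.442576264256205,0,0,0,5.551771863687086,1.5943006798806176,0,0,0,0.26905095152763436,0,0
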