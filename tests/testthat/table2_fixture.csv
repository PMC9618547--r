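parameter,value
drug_cost_nusinersen,110000
drug_cost_avxs101,3054344
admin_nusinersen_intrathecal_injection_cns,77.65
admin_nusinersen_intrathecal_injection_csf,164.4
admin_nusinersen_specialist,51.5
admin_nusinersen_monitor_thrombocytopenia,16.95
admin_nusinersen_monitor_renal_toxicity,9.7
admin_nusinersen_anaesthesia_lumbar_puncture,102
admin_nusinersen_imaging,34.3
admin_nusinersen_inpatient_per_diem,1839
admin_nusinersen_inpatient_anaesthesia,281
admin_avxs101_iv_infusion,67.1
admin_avxs101_anti_aav9_test,15.65
admin_avxs101_laboratory_monitoring,17.7
admin_avxs101_prednisolone,14.53
state_cost_not_sitting,23569
state_cost_sitting,9896
state_cost_walking,6644
state_cost_pav,27693
utility_not_sitting,0.104
utility_sitting,0.115
utility_walking,0.252
utility_pav,0.104
utility_sd_not_sitting,0.0278
utility_sd_sitting,0.0227
utility_sd_walking,0.0332
utility_sd_pav,0.0278
p_ns_death_soc,0.0532
p_ns_death_treatment,0.0184
p_ns_pav_soc,0.0625
p_ns_pav_treatment,0.0355
p_pav_death,0.0146
weibull_lambda,0.0006
weibull_p,1.9613
discount_costs,0.05
discount_effects,0.05
horizon_years,100
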