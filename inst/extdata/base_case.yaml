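horizon_years: 100.0
start_age: 0.0
discount:
  costs: 0.05
  effects: 0.05
  cycle_length_months: 1.0
costs:
  state:
    not_sitting: 23569.0
    sitting: 9896.0
    walking: 6644.0
    pav: 27693.0
    dead: 0.0
  state_interval:
    not_sitting:
    - 16498.0
    - 30640.0
    sitting:
    - 6927.0
    - 12865.0
    walking:
    - 4651.0
    - 8637.0
    pav:
    - 19385.0
    - 36001.0
  drug:
    nusinersen: 110000.0
    avxs101: 3054344.0
  drug_interval:
    nusinersen:
    - 78804.0
    - 146349.450000000011642
    avxs101:
    - 2138121.0
    - 3970796.0
  admin_items:
    nusinersen:
      intrathecal_injection_cns: 77.650000000000006
      intrathecal_injection_csf: 164.400000000000006
      specialist: 51.5
      monitor_thrombocytopenia: 16.949999999999999
      monitor_renal_toxicity: 9.699999999999999
      anaesthesia_lumbar_puncture: 102.0
      imaging: 34.299999999999997
      inpatient_per_diem: 1839.0
      inpatient_anaesthesia: 281.0
    avxs101:
      iv_infusion: 67.099999999999994
      anti_aav9_test: 15.65
      laboratory_monitoring: 17.699999999999999
      prednisolone: 14.529999999999999
utilities:
  mean:
    not_sitting: 0.104
    sitting: 0.115
    walking: 0.252
    pav: 0.104
    dead: 0.0
  sd:
    not_sitting: 0.0278
    sitting: 0.0227
    walking: 0.0332
    pav: 0.0278
    dead: 0.0
transitions:
  soc:
    ns_death: 0.0532
    ns_pav: 0.0625
  treatment:
    ns_death: 0.0184
    ns_pav: 0.0355
  pav_death: 0.0146
  intervals:
    soc_ns_death:
    - 0.0372
    - 0.0692
    trt_ns_death:
    - 0.0129
    - 0.0239
    soc_ns_pav:
    - 0.0437
    - 0.0812
    trt_ns_pav:
    - 0.0248
    - 0.0461
    pav_death:
    - 0.0102
    - 0.019
  weibull:
    lambda: 0.0006
    p: 1.9613
    time_unit: years
    lambda_interval:
    - 0.0002
    - 0.0017
    p_interval:
    - 1.7226
    - 2.2331
  lifetable:
    age:
    - 0.0
    - 1.0
    - 2.0
    - 3.0
    - 4.0
    - 5.0
    - 6.0
    - 7.0
    - 8.0
    - 9.0
    - 10.0
    - 11.0
    - 12.0
    - 13.0
    - 14.0
    - 15.0
    - 16.0
    - 17.0
    - 18.0
    - 19.0
    - 20.0
    - 21.0
    - 22.0
    - 23.0
    - 24.0
    - 25.0
    - 26.0
    - 27.0
    - 28.0
    - 29.0
    - 30.0
    - 31.0
    - 32.0
    - 33.0
    - 34.0
    - 35.0
    - 36.0
    - 37.0
    - 38.0
    - 39.0
    - 40.0
    - 41.0
    - 42.0
    - 43.0
    - 44.0
    - 45.0
    - 46.0
    - 47.0
    - 48.0
    - 49.0
    - 50.0
    - 51.0
    - 52.0
    - 53.0
    - 54.0
    - 55.0
    - 56.0
    - 57.0
    - 58.0
    - 59.0
    - 60.0
    - 61.0
    - 62.0
    - 63.0
    - 64.0
    - 65.0
    - 66.0
    - 67.0
    - 68.0
    - 69.0
    - 70.0
    - 71.0
    - 72.0
    - 73.0
    - 74.0
    - 75.0
    - 76.0
    - 77.0
    - 78.0
    - 79.0
    - 80.0
    - 81.0
    - 82.0
    - 83.0
    - 84.0
    - 85.0
    - 86.0
    - 87.0
    - 88.0
    - 89.0
    - 90.0
    - 91.0
    - 92.0
    - 93.0
    - 94.0
    - 95.0
    - 96.0
    - 97.0
    - 98.0
    - 99.0
    - 100.0
    - 101.0
    - 102.0
    - 103.0
    - 104.0
    - 105.0
    - 106.0
    - 107.0
    - 108.0
    - 109.0
    - 110.0
    qx:
    - 0.000219975801775
    - 0.000221975359823
    - 0.000224174869058
    - 0.000226594323627
    - 0.000229255716891
    - 0.000232183241298
    - 0.000235403508245
    - 0.000238945789906
    - 0.000242842285238
    - 0.000247128412562
    - 0.000251843131395
    - 0.000257029296431
    - 0.000262734046898
    - 0.000269009234813
    - 0.000275911896026
    - 0.000283504768314
    - 0.000291856861225
    - 0.000301044082834
    - 0.000311149929087
    - 0.000322266241972
    - 0.000334494043376
    - 0.000347944452169
    - 0.000362739692817
    - 0.000379014204614
    - 0.000396915861566
    - 0.000416607313931
    - 0.0004382674635
    - 0.000462093085918
    - 0.000488300614644
    - 0.000517128102582
    - 0.000548837379013
    - 0.000583716421161
    - 0.00062208196164
    - 0.000664282355116
    - 0.000710700729753
    - 0.000761758451564
    - 0.000817918932462
    - 0.000879691815809
    - 0.000947637576541
    - 0.001022372576459
    - 0.001104574619221
    - 0.001194989053756
    - 0.001294435479472
    - 0.001403815111654
    - 0.001524118870886
    - 0.001656436266299
    - 0.00180196514886
    - 0.001962022417862
    - 0.002138055771338
    - 0.00233165659917
    - 0.002544574126431
    - 0.002778730923795
    - 0.003036239911874
    - 0.003319422996944
    - 0.003630831486799
    - 0.003973268447363
    - 0.004349813173145
    - 0.004763847957559
    - 0.005219087362517
    - 0.005719610200312
    - 0.006269894454483
    - 0.00687485537989
    - 0.00753988703517
    - 0.008270907512842
    - 0.009074408142884
    - 0.009957506954008
    - 0.010928006682344
    - 0.011994457618578
    - 0.013166225580699
    - 0.014453565288653
    - 0.015867699397575
    - 0.017420903415495
    - 0.019126596686689
    - 0.020999439559908
    - 0.023055436777453
    - 0.025312047011819
    - 0.027788298335851
    - 0.030504909233407
    - 0.033484414532955
    - 0.036751295367442
    - 0.040332111920298
    - 0.04425563729819
    - 0.048552990363496
    - 0.053257764749675
    - 0.058406150555765
    - 0.064037044356632
    - 0.070192142157608
    - 0.076916008750716
    - 0.084256115582005
    - 0.092262837706248
    - 0.100989398683571
    - 0.110491750369083
    - 0.120828372481461
    - 0.132059974649598
    - 0.144249081393215
    - 0.157459478294277
    - 0.171755495605417
    - 0.187201103919818
    - 0.203858795562642
    - 0.221788225406473
    - 0.241044586304716
    - 0.261676697820442
    - 0.283724793050463
    - 0.307217997845715
    - 0.332171510417976
    - 0.358583508024631
    - 0.386431831894221
    - 0.415670532353496
    - 0.446226393416212
    - 0.477995599440806
    - 0.510840754469304
strategies:
  SOC:
    name: SOC
    arm: soc
    acquisition_cost: 0.0
    admin_cost: 0.0
    loading_months: []
    maintenance_start_month: .na.real
    maintenance_interval_months: .na.real
    one_off: no
    dose_states:
    - not_sitting
    - sitting
    - walking
    milestone_sit: 0.0
    milestone_walk: 0.0
    milestone_window_cycles: 0
    suppress_trial_mortality: no
  nusinersen:
    name: nusinersen
    arm: treatment
    acquisition_cost: 110000.0
    admin_cost: 2576.5
    loading_months:
    - 0.0
    - 0.5
    - 1.0
    - 2.0
    maintenance_start_month: 6.0
    maintenance_interval_months: 4.0
    one_off: no
    dose_states:
    - not_sitting
    - sitting
    - walking
    milestone_sit: 0.08
    milestone_walk: 0.0
    milestone_window_cycles: 13
    suppress_trial_mortality: no
  AVXS-101:
    name: AVXS-101
    arm: treatment
    acquisition_cost: 3054344.0
    admin_cost: 114.97999999999999
    loading_months: 0.0
    maintenance_start_month: .na.real
    maintenance_interval_months: .na.real
    one_off: yes
    dose_states:
    - not_sitting
    - sitting
    - walking
    milestone_sit: 0.916666666666667
    milestone_walk: 0.166666666666667
    milestone_window_cycles: 24
    suppress_trial_mortality: yes
half_cycle_correction: yes

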