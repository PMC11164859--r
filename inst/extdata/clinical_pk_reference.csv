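population,label,dose_mg,route,parameter,observed,predicted,printed_ratio
healthy,iv_100,100,iv_bolus,cmax,3.796,4.065,0.933
healthy,iv_100,100,iv_bolus,auc_0_inf,31.42,19.524,1.6
healthy,iv_100,100,iv_bolus,cl,3.182,6.121,NA
healthy,oral_100_s21,100,oral,cmax,2.19,2.14,NA
healthy,oral_100_s21,100,oral,auc_0_inf,32.75,27.0,1.2
healthy,oral_100_s21,100,oral,cl,3.05,3.69,0.82
healthy,oral_10_s21,10,oral,auc_0_inf,2.58,2.59,NA
healthy,oral_10_s21,10,oral,cl,3.86,3.85,NA
cirrhosis,cp_a_100,100,oral,cmax,2.2369,1.840,1.2
cirrhosis,cp_a_100,100,oral,auc_0_inf,44.51,43.0,1.0
cirrhosis,cp_a_100,100,oral,cl,2.398,2.312,1.03
cirrhosis,cp_b_100,100,oral,cmax,3.062,1.916,NA
cirrhosis,cp_b_100,100,oral,auc_0_inf,42.50,39.12,1.1
cirrhosis,cp_b_100,100,oral,cl,2.207,2.510,0.9
cirrhosis,cp_c_100,100,oral,cmax,2.541,1.597,1.6
cirrhosis,cp_c_100,100,oral,auc_0_inf,46.30,36.90,1.25
cirrhosis,cp_c_100,100,oral,cl,2.167,2.910,0.74
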