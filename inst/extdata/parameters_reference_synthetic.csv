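"name","value","unit","source"
"V_egfr",6,"1/h","fitted"
"V_raf",6,"1/h","fitted"
"V_erk",4,"1/h","fitted"
"V_kinasex",3,"1/h","fitted"
"V_rac",2,"1/h","fitted"
"V_pak",2,"1/h","fitted"
"V_pi3k",1,"1/h","fitted"
"V_akt",1,"1/h","fitted"
"V_camp",2,"1/h","fitted"
"V_pka",2,"1/h","fitted"
"V_creb",1,"1/h","fitted"
"V_bad112",0.1,"1/h","fitted"
"V_bad136_pak",0.1,"1/h","fitted"
"V_bad136_akt",0.2,"1/h","fitted"
"K_egfr",0.5,"dimensionless","fitted"
"K_raf",0.5,"dimensionless","fitted"
"K_erk",0.5,"dimensionless","fitted"
"K_kinasex",0.5,"dimensionless","fitted"
"K_rac",0.5,"dimensionless","fitted"
"K_pak",0.5,"dimensionless","fitted"
"K_pi3k",0.5,"dimensionless","fitted"
"K_akt",0.7,"dimensionless","fitted"
"K_camp",10,"dimensionless","fitted"
"K_pka",0.5,"dimensionless","fitted"
"K_creb",0.5,"dimensionless","fitted"
"K_bad112",0.5,"dimensionless","fitted"
"K_bad136_pak",0.5,"dimensionless","fitted"
"K_bad136_akt",0.7,"dimensionless","fitted"
"n_egfr",2,"dimensionless","fixed"
"n_raf",2,"dimensionless","fixed"
"n_erk",2,"dimensionless","fixed"
"n_kinasex",2,"dimensionless","fixed"
"n_rac",2,"dimensionless","fixed"
"n_pak",2,"dimensionless","fixed"
"n_pi3k",1,"dimensionless","fixed"
"n_akt",2,"dimensionless","fixed"
"n_camp",1,"dimensionless","fixed"
"n_pka",2,"dimensionless","fixed"
"n_creb",2,"dimensionless","fixed"
"n_bad112",2,"dimensionless","fixed"
"n_bad136_pak",2,"dimensionless","fixed"
"n_bad136_akt",2,"dimensionless","fixed"
"d_EGFR",5,"1/h^2","fitted"
"d_Raf",5,"1/h^2","fitted"
"d_ERK",5,"1/h^2","fitted"
"d_KinaseX",5,"1/h^2","fitted"
"d_Rac",2,"1/h","fitted"
"d_PAK",2,"1/h","fitted"
"d_cAMP",1,"1/h","fitted"
"d_PKA",1,"1/h","fitted"
"d_CREB",1,"1/h","fitted"
"k_a",0.001,"1/h^2","fitted"
"bad_total",2.5,"dimensionless","fitted"
"K_bad",0.25,"dimensionless","fitted"
"n_bad",2,"dimensionless","fixed"
"K_mcl",0.3,"dimensionless","fitted"
"n_mcl",2,"dimensionless","fixed"
"beta_mcl",0.5,"dimensionless","fitted"
"d_PI3K",0.666666666666667,"1/h","derived"
"d_AKT",0.671140939597315,"1/h","derived"
"d_pS112BAD",0.05,"1/h","derived"
"d_pS136BAD",0.134228187919463,"1/h","derived"
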