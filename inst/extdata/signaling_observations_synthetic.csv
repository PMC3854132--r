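"condition_id","schedule","readout","time","value","rule","replicate","horizon"
"EPI_control","control","pS112BAD",3,0.927465758037123,"to_control",1,3
"EPI_control","control","pCREB",3,0,"to_max",1,3
"EPI_LY","LY294002:10@0","pS112BAD",3,1.03525396981889,"to_control",1,3
"EPI_LY","LY294002:10@0","pCREB",3,0,"to_max",1,3
"EPI_LY_epi0.01","LY294002:10@0+STRESS:0.144025@2","pS112BAD",3,0.803321806865936,"to_control",1,3
"EPI_LY_epi0.01","LY294002:10@0+STRESS:0.144025@2","pCREB",3,1.70408013175611e-06,"to_max",1,3
"EPI_LY_epi0.1","LY294002:10@0+STRESS:1.37956@2","pS112BAD",3,0.824632268077926,"to_control",1,3
"EPI_LY_epi0.1","LY294002:10@0+STRESS:1.37956@2","pCREB",3,0.00799271534747507,"to_max",1,3
"EPI_LY_epi1","LY294002:10@0+STRESS:10.0329@2","pS112BAD",3,0.938146748490733,"to_control",1,3
"EPI_LY_epi1","LY294002:10@0+STRESS:10.0329@2","pCREB",3,0.474337191062532,"to_max",1,3
"EPI_LY_epi10","LY294002:10@0+STRESS:34.7081@2","pS112BAD",3,0.96380382540167,"to_control",1,3
"EPI_LY_epi10","LY294002:10@0+STRESS:34.7081@2","pCREB",3,0.935561907266328,"to_max",1,3
"EPI_LY_epi100","LY294002:10@0+STRESS:66.801@2","pS112BAD",3,0.997751790074176,"to_control",1,3
"EPI_LY_epi100","LY294002:10@0+STRESS:66.801@2","pCREB",3,1,"to_max",1,3
"EPI_LY_epi1000","LY294002:10@0+STRESS:100@2","pS112BAD",3,0.840801451315271,"to_control",1,3
"EPI_LY_epi1000","LY294002:10@0+STRESS:100@2","pCREB",3,0.86087245568068,"to_max",1,3
"TC_control","control","pAKT_S473",2,0.955548345066205,"to_control",1,4.5
"TC_control","control","pERK",2,0,"to_total",1,4.5
"TC_control","control","pS112BAD",2,0.902286965310021,"to_control",1,4.5
"TC_control","control","pS136BAD",2,1.17706244515322,"to_control",1,4.5
"TC_EGF_0.166667h","EGF:1@0","pAKT_S473",0.166666666666667,1.06076209053117,"to_control",1,4.5
"TC_EGF_0.166667h","EGF:1@0","pERK",0.166666666666667,0.040869587432954,"to_total",1,4.5
"TC_EGF_0.166667h","EGF:1@0","pS112BAD",0.166666666666667,1.01326998459083,"to_control",1,4.5
"TC_EGF_0.166667h","EGF:1@0","pS136BAD",0.166666666666667,0.939773774494685,"to_control",1,4.5
"TC_EGF_0.5h","EGF:1@0","pAKT_S473",0.5,1.01206964553466,"to_control",1,4.5
"TC_EGF_0.5h","EGF:1@0","pERK",0.5,0.799340167652227,"to_total",1,4.5
"TC_EGF_0.5h","EGF:1@0","pS112BAD",0.5,1.20943193152678,"to_control",1,4.5
"TC_EGF_0.5h","EGF:1@0","pS136BAD",0.5,1.1463501603641,"to_control",1,4.5
"TC_EGF_1h","EGF:1@0","pAKT_S473",1,1.11635855392802,"to_control",1,4.5
"TC_EGF_1h","EGF:1@0","pERK",1,0.70475511669,"to_total",1,4.5
"TC_EGF_1h","EGF:1@0","pS112BAD",1,1.15978797306601,"to_control",1,4.5
"TC_EGF_1h","EGF:1@0","pS136BAD",1,1.11225364687863,"to_control",1,4.5
"TC_EGF_2h","EGF:1@0","pAKT_S473",2,1.06558634897649,"to_control",1,4.5
"TC_EGF_2h","EGF:1@0","pERK",2,0.163105808546399,"to_total",1,4.5
"TC_EGF_2h","EGF:1@0","pS112BAD",2,1.08501477871591,"to_control",1,4.5
"TC_EGF_2h","EGF:1@0","pS136BAD",2,1.20404067323908,"to_control",1,4.5
"TC_LY","LY294002:10@0","pAKT_S473",2,0.736431754394287,"to_control",1,4.5
"TC_LY","LY294002:10@0","pERK",2,0,"to_total",1,4.5
"TC_LY","LY294002:10@0","pS112BAD",2,0.914859570419949,"to_control",1,4.5
"TC_LY","LY294002:10@0","pS136BAD",2,0.975695525128325,"to_control",1,4.5
"TC_LY_EGF_0.166667h","LY294002:10@0+EGF:1@2","pAKT_S473",2.16666666666667,0.627418674165262,"to_control",1,4.5
"TC_LY_EGF_0.166667h","LY294002:10@0+EGF:1@2","pERK",2.16666666666667,0.0485020250784326,"to_total",1,4.5
"TC_LY_EGF_0.166667h","LY294002:10@0+EGF:1@2","pS112BAD",2.16666666666667,0.879842323592625,"to_control",1,4.5
"TC_LY_EGF_0.166667h","LY294002:10@0+EGF:1@2","pS136BAD",2.16666666666667,1.04281569423123,"to_control",1,4.5
"TC_LY_EGF_0.5h","LY294002:10@0+EGF:1@2","pAKT_S473",2.5,0.491856593086811,"to_control",1,4.5
"TC_LY_EGF_0.5h","LY294002:10@0+EGF:1@2","pERK",2.5,0.78307971872901,"to_total",1,4.5
"TC_LY_EGF_0.5h","LY294002:10@0+EGF:1@2","pS112BAD",2.5,1.05993433808481,"to_control",1,4.5
"TC_LY_EGF_0.5h","LY294002:10@0+EGF:1@2","pS136BAD",2.5,0.822242392596023,"to_control",1,4.5
"TC_LY_EGF_1h","LY294002:10@0+EGF:1@2","pAKT_S473",3,0.371871333398213,"to_control",1,4.5
"TC_LY_EGF_1h","LY294002:10@0+EGF:1@2","pERK",3,1.03487714191365,"to_total",1,4.5
"TC_LY_EGF_1h","LY294002:10@0+EGF:1@2","pS112BAD",3,1.04664213158195,"to_control",1,4.5
"TC_LY_EGF_1h","LY294002:10@0+EGF:1@2","pS136BAD",3,0.934754374446573,"to_control",1,4.5
"TC_LY_EGF_2h","LY294002:10@0+EGF:1@2","pAKT_S473",4,0.283418986203822,"to_control",1,4.5
"TC_LY_EGF_2h","LY294002:10@0+EGF:1@2","pERK",4,0.16666827085511,"to_total",1,4.5
"TC_LY_EGF_2h","LY294002:10@0+EGF:1@2","pS112BAD",4,0.904049978132315,"to_control",1,4.5
"TC_LY_EGF_2h","LY294002:10@0+EGF:1@2","pS136BAD",4,0.974675500914268,"to_control",1,4.5
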