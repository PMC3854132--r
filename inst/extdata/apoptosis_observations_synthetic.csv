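"condition_id","schedule","readout","time","value","rule","replicate","horizon"
"AP_control","control","apoptosis_pct",48,11.1428571428571,"none",1,48
"AP_control","control","apoptosis_pct",48,9.42857142857143,"none",2,48
"AP_control","control","apoptosis_pct",48,7.42857142857143,"none",3,48
"AP_LY","LY294002:1@0","apoptosis_pct",48,26,"none",1,48
"AP_LY","LY294002:1@0","apoptosis_pct",48,23.7142857142857,"none",2,48
"AP_LY","LY294002:1@0","apoptosis_pct",48,23.1428571428571,"none",3,48
"AP_LY_EGF","LY294002:1@0+EGF:1@0","apoptosis_pct",48,15.1428571428571,"none",1,48
"AP_LY_EGF","LY294002:1@0+EGF:1@0","apoptosis_pct",48,14.8571428571429,"none",2,48
"AP_LY_EGF","LY294002:1@0+EGF:1@0","apoptosis_pct",48,13.1428571428571,"none",3,48
"AP_LY_VIP","LY294002:1@0+STRESS:10@0","apoptosis_pct",48,4.57142857142857,"none",1,48
"AP_LY_VIP","LY294002:1@0+STRESS:10@0","apoptosis_pct",48,4.85714285714286,"none",2,48
"AP_LY_VIP","LY294002:1@0+STRESS:10@0","apoptosis_pct",48,4.85714285714286,"none",3,48
"AP_LY_C4BRaf","LY294002:1@0+C4BRaf:1@0","apoptosis_pct",48,20.5714285714286,"none",1,48
"AP_LY_C4BRaf","LY294002:1@0+C4BRaf:1@0","apoptosis_pct",48,25.1428571428571,"none",2,48
"AP_LY_C4BRaf","LY294002:1@0+C4BRaf:1@0","apoptosis_pct",48,23.7142857142857,"none",3,48
"AP_LY_DNPAK1","LY294002:1@0+DN-PAK1:1@0","apoptosis_pct",48,26.2857142857143,"none",1,48
"AP_LY_DNPAK1","LY294002:1@0+DN-PAK1:1@0","apoptosis_pct",48,22,"none",2,48
"AP_LY_DNPAK1","LY294002:1@0+DN-PAK1:1@0","apoptosis_pct",48,27.7142857142857,"none",3,48
"AP_LY_DNPAK1_C4BRaf","LY294002:1@0+DN-PAK1:1@0+C4BRaf:1@0","apoptosis_pct",48,25.1428571428571,"none",1,48
"AP_LY_DNPAK1_C4BRaf","LY294002:1@0+DN-PAK1:1@0+C4BRaf:1@0","apoptosis_pct",48,27.4285714285714,"none",2,48
"AP_LY_DNPAK1_C4BRaf","LY294002:1@0+DN-PAK1:1@0+C4BRaf:1@0","apoptosis_pct",48,25.7142857142857,"none",3,48
"AP_LY_BADS112A","LY294002:1@0+BADS112A:1@0","apoptosis_pct",48,40,"none",1,48
"AP_LY_BADS112A","LY294002:1@0+BADS112A:1@0","apoptosis_pct",48,38,"none",2,48
"AP_LY_BADS112A","LY294002:1@0+BADS112A:1@0","apoptosis_pct",48,36,"none",3,48
"AP_EGF_LY_C4BRaf_DNPAK1","EGF:1@0+LY294002:1@0+C4BRaf:1@0+DN-PAK1:1@0","apoptosis_pct",48,16.8571428571429,"none",1,48
"AP_EGF_LY_C4BRaf_DNPAK1","EGF:1@0+LY294002:1@0+C4BRaf:1@0+DN-PAK1:1@0","apoptosis_pct",48,16.2857142857143,"none",2,48
"AP_EGF_LY_C4BRaf_DNPAK1","EGF:1@0+LY294002:1@0+C4BRaf:1@0+DN-PAK1:1@0","apoptosis_pct",48,19.4285714285714,"none",3,48
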