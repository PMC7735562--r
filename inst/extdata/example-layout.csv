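plate,well,field,channel,path,treatment,dose_uM,role
P1,A01,1,GFP,P1_A01_f1_gfp.tif,vehicle,0,vehicle
P1,A01,1,HOECHST,P1_A01_f1_hoechst.tif,vehicle,0,vehicle
P1,A01,2,GFP,P1_A01_f2_gfp.tif,vehicle,0,vehicle
P1,A01,2,HOECHST,P1_A01_f2_hoechst.tif,vehicle,0,vehicle
P1,B01,1,GFP,P1_B01_f1_gfp.tif,mo56HC,0.03,marginal_positive
P1,B01,1,HOECHST,P1_B01_f1_hoechst.tif,mo56HC,0.03,marginal_positive
P1,B01,2,GFP,P1_B01_f2_gfp.tif,mo56HC,0.03,marginal_positive
P1,B01,2,HOECHST,P1_B01_f2_hoechst.tif,mo56HC,0.03,marginal_positive
P1,C01,1,GFP,P1_C01_f1_gfp.tif,mo56HC,3,positive_control
P1,C01,1,HOECHST,P1_C01_f1_hoechst.tif,mo56HC,3,positive_control
P1,C01,2,GFP,P1_C01_f2_gfp.tif,mo56HC,3,positive_control
P1,C01,2,HOECHST,P1_C01_f2_hoechst.tif,mo56HC,3,positive_control
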