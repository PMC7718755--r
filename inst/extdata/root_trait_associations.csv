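trait,marker,lg,pos_cM,effect,p,maf,below_bonferroni,replicate
RSA_5,avgbs_29471.1.50,Mrg09,44.7,-7.0,3.40e-06,0.35,FALSE,taipei
RSA_5,avgbs_cluster_34557.1.39,Mrg09,44.7,-6.5,1.19e-05,0.38,FALSE,taipei
RSA_5,avgbs2_169620.1.39,Mrg09,44.7,-6.5,1.19e-05,0.38,FALSE,taipei
RSA_5,avgbs_cluster_33692.1.63,Mrg09,47.1,-6.8,4.36e-06,0.39,FALSE,taipei
RG_4,GMI_ES01_c5178_479,Mrg04,45.0,2.2,2.47e-05,0.20,FALSE,taipei
RG_4,avgbs_115262.1.42,Mrg05,114.7,-4.0,5.17e-08,0.06,TRUE,taipei
RG_4,avgbs2_46371.1.64,Mrg05,131.6,6.3,2.12e-05,0.06,FALSE,taipei
RG_4,avgbs2_46371.1.8,Mrg05,131.6,6.3,2.12e-05,0.06,FALSE,taipei
RG_4,avgbs_12458.1.21,Mrg09,29.6,-2.8,2.33e-06,0.31,FALSE,taipei
RG_4,avgbs_205346.1.41,Mrg12,57.4,3.0,6.68e-08,0.36,TRUE,taipei
RG_4,avgbs_cluster_34786.1.14,Mrg17,87.1,3.1,3.86e-08,0.19,TRUE,taipei
RG_4,avgbs_218823,Mrg18,10.9,-1.6,1.50e-05,0.38,FALSE,taipei
RG_4,avgbs_cluster_38064.1.46,Mrg18,12.8,-2.4,2.98e-05,0.08,FALSE,taipei
RG_4,avgbs_cluster_37097.2.27,Mrg23,22.3,-2.1,4.49e-05,0.29,FALSE,taipei
RG_4,avgbs2_102913.1.47,Mrg28,57.3,-3.4,2.43e-05,0.09,FALSE,taipei
RG_4,avgbs2_10058.2.59,UKN,NA,4.9,2.51e-06,0.06,FALSE,taipei
RG_5,avgbs_cluster_26155.1.55,Mrg02,72.7,2.6,2.40e-05,0.37,FALSE,taipei
RG_5,avgbs2_122749.1.55,Mrg02,72.7,2.6,2.40e-05,0.37,FALSE,taipei
RG_5,avgbs_cluster_35609.1.46,Mrg02,87.3,-1.3,2.33e-06,0.40,FALSE,taipei
RG_5,avgbs_49723.1.14,Mrg08,129.6,2.6,2.15e-06,0.29,TRUE,taipei
RG_5,avgbs_21913.1.62,Mrg13,35.9,2.3,2.39e-06,0.35,FALSE,taipei
RG_5,avgbs_cluster_41284.1.50,Mrg15,32.7,-1.9,1.66e-05,0.42,FALSE,taipei
RG_5,avgbs_92060.1.20,Mrg18,40.0,-1.8,3.21e-05,0.31,FALSE,taipei
RG_5,avgbs_cluster_25488.1.14,Mrg21,146.0,-3.1,2.42e-07,0.16,TRUE,taipei
RG_5,avgbs_120739.1.46,Mrg24,41.8,-2.8,7.76e-06,0.09,FALSE,taipei
RG_5,avgbs_218324,Mrg28,17.1,-2.6,3.32e-05,0.07,FALSE,taipei
RRGR_4,GMI_DS_LB_8372,Mrg13,59.6,-0.047,8.46e-07,0.27,TRUE,taipei
RRGR_4,avgbs_cluster_15604.1.25,Mrg17,55.6,-0.055,2.38e-05,0.09,FALSE,taipei
RRGR_4,avgbs2_53658.1.10,Mrg18,60.3,-0.104,1.26e-08,0.08,TRUE,taipei
RRGR_4,avgbs_56897.1.18,Mrg28,36.8,-0.086,3.51e-05,0.18,FALSE,taipei
RRGR_4,avgbs_cluster_31411.1.54,Mrg28,43.8,-0.088,5.36e-08,0.17,TRUE,taipei
RRGR_4,avgbs_cluster_29960.1.24,Mrg28,43.8,0.044,1.03e-05,0.15,FALSE,taipei
RRGR_4,GMI_GBS_13776,Mrg28,43.8,-0.084,3.06e-05,0.19,FALSE,taipei
RRGR_4,GMI_GBS_96525,Mrg28,43.8,-0.085,2.89e-05,0.19,FALSE,taipei
RRGR_5,avgbs_cluster_10425.1.7,Mrg01,57.2,0.019,6.77e-06,0.46,FALSE,taipei
RRGR_5,avgbs_200217,Mrg04,50.3,0.021,9.28e-07,0.34,TRUE,taipei
RRGR_5,avgbs_cluster_10309.1.10,Mrg06,28.1,0.021,3.43e-07,0.44,TRUE,taipei
RRGR_5,avgbs_cluster_10035.1.11,Mrg13,106.5,0.020,1.84e-05,0.22,FALSE,taipei
RRGR_5,avgbs_207710,UKN,NA,-0.029,1.41e-06,0.10,TRUE,taipei
AVRSA,avgbs_29471.1.50,Mrg09,44.7,-2.1,3.00e-06,0.35,FALSE,taipei
AVRSA,avgbs_cluster_33692.1.63,Mrg09,47.1,-1.9,1.17e-05,0.39,FALSE,taipei
AVRSA,avgbs_cluster_28147.1.55,Mrg17,84.3,1.9,9.04e-06,0.46,FALSE,taipei
AVRSA,GMI_ES03_c19505_223,Mrg17,85.3,1.9,6.90e-06,0.49,FALSE,taipei
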