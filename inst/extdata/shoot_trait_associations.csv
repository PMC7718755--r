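trait,marker,lg,pos_cM,effect,p,maf,below_bonferroni,replicate
SL_5,avgbs_cluster_3321.1.50,Mrg11,69.3,-2.8,3.75e-06,0.18,FALSE,taipei
SL_5,avgbs_cluster_19949.1.14,Mrg15,87.2,-2.5,4.19e-07,0.44,TRUE,taipei
SL_5,avgbs2_169934.1.10,Mrg24,41.3,-3.1,7.46e-06,0.12,FALSE,taipei
SRGR_5,GMI_ES17_c1687_437,Mrg01,39.3,-0.058,1.82e-05,0.15,FALSE,aberdeen
SRGR_5,avgbs_22768,Mrg02,27.3,0.039,6.43e-07,0.23,TRUE,taipei
SRGR_5,avgbs_cluster_38112.1.47,Mrg03,55.8,-0.035,3.20e-06,0.34,FALSE,taipei
SRGR_5,avgbs_cluster_49442.1.14,Mrg03,77.8,-0.061,3.82e-06,0.12,FALSE,aberdeen
SRGR_5,GMI_ES03_c5596_272,Mrg03,101.6,0.027,2.96e-06,0.43,FALSE,taipei
SRGR_5,avgbs_cluster_1872.1.10,Mrg04,40.2,-0.027,3.43e-05,0.44,FALSE,taipei
SRGR_5,avgbs2_96578.1.61,Mrg09,78.3,-0.085,4.38e-06,0.15,FALSE,aberdeen
SRGR_5,avgbs_125970.1.51,Mrg11,42.0,0.029,4.79e-06,0.41,FALSE,taipei
SRGR_5,avgbs_cluster_3597.1.11,Mrg12,33.4,-0.062,3.28e-08,0.25,TRUE,aberdeen
SRGR_5,avgbs2_183559.1.25,Mrg12,40.2,-0.047,3.49e-07,0.19,TRUE,taipei
SRGR_5,avgbs_cluster_19949.1.14,Mrg15,87.2,-0.034,1.53e-07,0.44,TRUE,taipei
SRGR_5,avgbs_cluster_26077.1.22,Mrg20,226.6,-0.022,2.57e-05,0.44,FALSE,taipei
SRGR_5,avgbs_220709.1.57,Mrg21,22.7,-0.042,1.52e-06,0.21,TRUE,taipei
SRGR_5,avgbs_310061,UKN,NA,-0.122,3.36e-07,0.25,TRUE,aberdeen
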