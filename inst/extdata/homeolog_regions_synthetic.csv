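set_id,region_id,lg,start_cM,end_cM
setA,Mrg02_60_90,Mrg02,60,90
setA,Mrg12_40_60,Mrg12,40,60
setB,Mrg05_100_140,Mrg05,100,140
setB,Mrg06_10_40,Mrg06,10,40
setC,Mrg15_20_45,Mrg15,20,45
setC,Mrg23_10_35,Mrg23,10,35
setC,Mrg28_10_60,Mrg28,10,60
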