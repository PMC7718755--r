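trait,location,mean
RSA_4,taipei,125.9
RSA_5,taipei,154.7
RG_5,taipei,28.8
RSA_4,aberdeen,81.4
RSA_5,aberdeen,100.4
RG_5,aberdeen,19.0
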