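platform,n_markers
iSelect_6K,4561
GBS,18206
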