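region,mean_ml,sd_ml
TLV,91,5.4
PER,34.3,6.8
CER,4.75,0.9
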