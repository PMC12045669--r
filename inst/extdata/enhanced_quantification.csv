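specimen,enhanced_volume_ml,t1_post_ms,concentration_mm,gd_amount_umol
1,31.8,170,4.6,146.3
2,39.1,285.3,1.8,70.4
3,45.8,318.9,1.4,64.1
4,30.9,166.5,4.6,142.1
5,37.7,259.7,2.5,94.3
6,48.9,397,0.9,44
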