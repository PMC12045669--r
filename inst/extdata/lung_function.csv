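specimen,delta_p_cmh2o,compliance_ml_per_cmh2o
1,-97,0.138
2,-94,0.134
3,-79,0.134
4,-110,0.098
5,-62,0.165
6,-89,0.131
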