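specimen,pdf_percent,pvf_percent
1,83.0,35.7
2,87.4,38.8
3,79.1,23.6
4,92.1,29.4
5,78.1,33.7
6,84.6,33.7
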