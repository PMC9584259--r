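patient_id,group,show_prob
a,nonB,0.90
b,nonB,0.90
c,B,0.55
d,B,0.50
e,B,0.50
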