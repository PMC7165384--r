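group,birth_n,diagnosis_n
all,4198,5947
leukaemia,1384,1880
lymphoma,459,772
cns,902,1290
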