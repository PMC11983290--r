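category,n_patients,n_oud_icd_2day,n_sud_icd_2day
no,49,0,1
some,33,1,5
high,17,1,8
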