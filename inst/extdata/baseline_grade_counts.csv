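cohort,grade_group,n
jh,1,1428
jh,2,6
ucsf,1,1437
ucsf,2,178
ucsf,3,25
ucsf,4,4
uoft,1,1095
uoft,2,139
uoft,NA,9
prias,1,4654
prias,2,42
prias,3,1
prias,NA,3
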