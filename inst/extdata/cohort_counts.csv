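# Training-cohort demographic counts, one row per reason-for-amputation
# stratum: socket counts by sex, prescribed design and K-level. The
# "unrecorded" row holds the sockets absent from the reason strata so that
# column totals match the overall cohort (n=163, PTB 135 / TSB 21 / PTB-SC 7,
# K-level counts 22/61/74/6). Printed sex totals are internally inconsistent
# by one (F51 + M111 = 162); the unrecorded row preserves the female total.
reason,n,F,M,PTB,TSB,PTBSC,k1,k2,k3,k4
dysvascularity,63,11,52,59,3,1,15,41,6,1
trauma,47,17,30,32,14,1,3,10,31,3
infection,26,10,16,22,2,2,2,8,16,0
neuro,10,6,4,10,0,0,1,1,7,1
neoplasia,6,4,2,5,1,0,1,1,3,1
congenital,3,2,1,2,0,1,0,0,3,0
unrecorded,8,1,7,5,1,2,0,0,8,0
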