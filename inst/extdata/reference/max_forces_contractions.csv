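# Reference maximum muscle forces (F_H, N), contraction at maximum force (dq_H, m)
# and total contraction (dq_C, m) per food, muscle and chewing side
food,side,muscle,F_H_N,dq_H_m,dq_C_m
d,working,masseter,233.2,0.0021,0.0042
b,working,masseter,149.4,0.0044,0.0093
a,working,masseter,112.2,0.0024,0.0105
c,working,masseter,274.3,0.0024,0.0089
s,working,masseter,126.9,0.0029,0.0125
d,non_working,masseter,200.3,0.0025,0.0050
b,non_working,masseter,127.8,0.0053,0.0112
a,non_working,masseter,96.2,0.0029,0.0127
c,non_working,masseter,235.5,0.0028,0.0106
s,non_working,masseter,108.8,0.0035,0.0149
d,working,medial_pterygoid,209.3,0.0014,0.0027
b,working,medial_pterygoid,134.5,0.0028,0.0059
a,working,medial_pterygoid,100.6,0.0015,0.0067
c,working,medial_pterygoid,244.7,0.0015,0.0056
s,working,medial_pterygoid,113.5,0.0019,0.0080
d,non_working,medial_pterygoid,179.2,0.0017,0.0033
b,non_working,medial_pterygoid,115.4,0.0035,0.0073
a,non_working,medial_pterygoid,86.2,0.0019,0.0083
c,non_working,medial_pterygoid,209.8,0.0019,0.0069
s,non_working,medial_pterygoid,97.3,0.0023,0.0098
d,working,temporalis,46.1,0.0034,0.0067
b,working,temporalis,29.3,0.0073,0.0154
a,working,temporalis,22.7,0.0039,0.0169
c,working,temporalis,53.4,0.0030,0.0145
s,working,temporalis,24.4,0.0048,0.0206
d,non_working,temporalis,39.4,0.0042,0.0082
b,non_working,temporalis,25.0,0.0089,0.0188
a,non_working,temporalis,19.4,0.0047,0.0204
c,non_working,temporalis,45.9,0.0047,0.0175
s,non_working,temporalis,20.9,0.0058,0.0249
d,working,anterior_temporalis,22.1,0.0027,0.0054
b,working,anterior_temporalis,14.1,0.0058,0.0123
a,working,anterior_temporalis,10.9,0.0032,0.0139
c,working,anterior_temporalis,25.7,0.0033,0.0123
s,working,anterior_temporalis,11.7,0.0038,0.0163
d,non_working,anterior_temporalis,18.9,0.0034,0.0066
b,non_working,anterior_temporalis,12.0,0.0072,0.0151
a,non_working,anterior_temporalis,9.3,0.0039,0.0169
c,non_working,anterior_temporalis,22.0,0.0038,0.0145
s,non_working,anterior_temporalis,10.0,0.0046,0.0197
d,working,middle_temporalis,13.4,0.0025,0.0047
b,working,middle_temporalis,8.5,0.0052,0.0110
a,working,middle_temporalis,6.6,0.0029,0.0122
c,working,middle_temporalis,15.5,0.0030,0.0110
s,working,middle_temporalis,7.1,0.0034,0.0144
d,non_working,middle_temporalis,11.4,0.0029,0.0057
b,non_working,middle_temporalis,7.2,0.0063,0.0135
a,non_working,middle_temporalis,5.6,0.0033,0.0147
c,non_working,middle_temporalis,13.3,0.0033,0.0127
s,non_working,middle_temporalis,6.1,0.0040,0.0175
d,working,posterior_temporalis,10.6,0.0021,0.0041
b,working,posterior_temporalis,6.7,0.0044,0.0092
a,working,posterior_temporalis,5.2,0.0024,0.0104
c,working,posterior_temporalis,12.3,0.0025,0.0093
s,working,posterior_temporalis,5.6,0.0030,0.0129
d,non_working,posterior_temporalis,9.1,0.0025,0.0049
b,non_working,posterior_temporalis,5.7,0.0054,0.0114
a,non_working,posterior_temporalis,4.5,0.0029,0.0126
c,non_working,posterior_temporalis,10.6,0.0029,0.0108
s,non_working,posterior_temporalis,4.8,0.0035,0.0150
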