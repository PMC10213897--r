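# Reference muscle stiffness K = F_H / dq_H (N/m) per food, muscle and chewing side
food,side,muscle,K_N_per_m
d,working,masseter,108900
b,working,masseter,34000
a,working,masseter,46300
c,working,masseter,114800
s,working,masseter,43500
d,working,medial_pterygoid,152100
b,working,medial_pterygoid,48200
a,working,medial_pterygoid,65100
c,working,medial_pterygoid,162700
s,working,medial_pterygoid,60800
d,working,temporalis,13600
b,working,temporalis,4000
a,working,temporalis,5800
c,working,temporalis,13700
s,working,temporalis,5100
d,working,anterior_temporalis,10300
b,working,anterior_temporalis,3200
a,working,anterior_temporalis,4500
c,working,anterior_temporalis,10700
s,working,anterior_temporalis,4000
d,working,middle_temporalis,6200
b,working,middle_temporalis,1900
a,working,middle_temporalis,2700
c,working,middle_temporalis,6500
s,working,middle_temporalis,2400
d,working,posterior_temporalis,4900
b,working,posterior_temporalis,1500
a,working,posterior_temporalis,2200
c,working,posterior_temporalis,5100
s,working,posterior_temporalis,1900
d,non_working,masseter,78600
b,non_working,masseter,24100
a,non_working,masseter,32800
c,non_working,masseter,82700
s,non_working,masseter,31300
d,non_working,medial_pterygoid,106500
b,non_working,medial_pterygoid,33400
a,non_working,medial_pterygoid,45000
c,non_working,medial_pterygoid,113200
s,non_working,medial_pterygoid,42600
d,non_working,temporalis,9400
b,non_working,temporalis,2800
a,non_working,temporalis,4100
c,non_working,temporalis,9800
s,non_working,temporalis,3600
d,non_working,anterior_temporalis,7400
b,non_working,anterior_temporalis,2300
a,non_working,anterior_temporalis,3200
c,non_working,anterior_temporalis,7700
s,non_working,anterior_temporalis,2900
d,non_working,middle_temporalis,4500
b,non_working,middle_temporalis,1400
a,non_working,middle_temporalis,1900
c,non_working,middle_temporalis,4700
s,non_working,middle_temporalis,1700
d,non_working,posterior_temporalis,3600
b,non_working,posterior_temporalis,1100
a,non_working,posterior_temporalis,1500
c,non_working,posterior_temporalis,3700
s,non_working,posterior_temporalis,1400
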