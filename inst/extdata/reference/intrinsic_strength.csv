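# Reference intrinsic strength k = F_H / PCSA (N/m^2) per food, muscle and chewing side,
# with the physiological cross-sectional areas (PCSA, m^2) used
food,side,muscle,pcsa_m2,k_N_per_m2
d,working,masseter,6.80e-4,343000
b,working,masseter,6.80e-4,220000
a,working,masseter,6.80e-4,165000
c,working,masseter,6.80e-4,403000
s,working,masseter,6.80e-4,187000
d,working,medial_pterygoid,4.37e-4,479000
b,working,medial_pterygoid,4.37e-4,308000
a,working,medial_pterygoid,4.37e-4,230000
c,working,medial_pterygoid,4.37e-4,560000
s,working,medial_pterygoid,4.37e-4,260000
d,working,temporalis,8.23e-4,56000
b,working,temporalis,8.23e-4,36000
a,working,temporalis,8.23e-4,28000
c,working,temporalis,8.23e-4,65000
s,working,temporalis,8.23e-4,30000
d,non_working,masseter,6.80e-4,295000
b,non_working,masseter,6.80e-4,188000
a,non_working,masseter,6.80e-4,141000
c,non_working,masseter,6.80e-4,346000
s,non_working,masseter,6.80e-4,160000
d,non_working,medial_pterygoid,4.37e-4,410000
b,non_working,medial_pterygoid,4.37e-4,264000
a,non_working,medial_pterygoid,4.37e-4,197000
c,non_working,medial_pterygoid,4.37e-4,479000
s,non_working,medial_pterygoid,4.37e-4,223000
d,non_working,temporalis,8.23e-4,48000
b,non_working,temporalis,8.23e-4,30000
a,non_working,temporalis,8.23e-4,24000
c,non_working,temporalis,8.23e-4,56000
s,non_working,temporalis,8.23e-4,25000
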