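# Reference proportionality coefficients R_F = F_H / F_max per muscle and side.
# case I: principal muscle vectors; case II: temporalis split into three parts
side,muscle,case,R_F
working,masseter,I,1.215
working,medial_pterygoid,I,1.089
working,temporalis,I,0.239
working,anterior_temporalis,II,0.115
working,middle_temporalis,II,0.069
working,posterior_temporalis,II,0.055
non_working,masseter,I,1.042
non_working,medial_pterygoid,I,0.934
non_working,temporalis,I,0.204
non_working,anterior_temporalis,II,0.098
non_working,middle_temporalis,II,0.059
non_working,posterior_temporalis,II,0.047
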