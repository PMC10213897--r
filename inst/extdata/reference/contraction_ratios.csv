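# Reference proportionality coefficients R_q = dq_C / h per muscle and side.
# case I: principal muscle vectors; case II: temporalis split into three parts
side,muscle,case,R_q
working,masseter,I,0.46
working,medial_pterygoid,I,0.29
working,temporalis,I,0.74
working,anterior_temporalis,II,0.60
working,middle_temporalis,II,0.53
working,posterior_temporalis,II,0.46
non_working,masseter,I,0.55
non_working,medial_pterygoid,I,0.36
non_working,temporalis,I,0.90
non_working,anterior_temporalis,II,0.73
non_working,middle_temporalis,II,0.64
non_working,posterior_temporalis,II,0.55
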