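# Rule Set 1 on-target activity model coefficients (logistic regression).
# Positions are 1-based over the 30-mer context (4 nt upstream + 20 nt
# protospacer + 3 nt PAM + 3 nt downstream); protospacer occupies 5-24,
# PAM 25-27. The GC term counts G+C over the protospacer: gc_low applies
# per base of GC deficit below 10/20, gc_high per base of excess above
# 10/20. This table omits the NGGX interaction feature.
feature_kind	position	sequence	weight
intercept	NA	NA	0.597636154
gc_low	NA	NA	-0.202625894
gc_high	NA	NA	-0.166587752
single	2	G	-0.275377128
single	3	A	-0.323887456
single	3	C	0.172128871
single	4	C	-0.100666209
single	5	C	-0.20180294
single	5	G	0.245956633
single	6	A	0.036440041
single	6	C	0.098376835
single	7	C	-0.741181291
single	7	G	-0.393264397
single	12	A	-0.466099015
single	15	A	0.085376945
single	15	C	-0.013813972
single	16	A	0.272620512
single	16	C	-0.119022648
single	16	T	-0.285944222
single	17	A	0.097454592
single	17	G	-0.17554617
single	18	C	-0.345795451
single	18	G	-0.678096426
single	19	A	0.22508903
single	19	C	-0.507794051
single	20	G	-0.417373597
single	20	T	-0.054306959
single	21	G	0.379899366
single	21	T	-0.090712644
single	22	C	0.057823319
single	22	T	-0.530567296
single	23	T	-0.877007428
single	24	C	-0.876235846
single	24	G	0.278916259
single	25	A	-0.403102218
single	25	C	0.287935617
single	25	T	-0.221637217
single	28	G	-0.689016682
single	28	T	0.117877577
single	29	C	-0.160445304
single	30	G	0.386342585
dinuc	2	GT	-0.625778696
dinuc	5	GC	0.300043317
dinuc	6	AA	-0.834836245
dinuc	6	TA	0.760627772
dinuc	7	GG	-0.490816749
dinuc	12	GG	-1.516907439
dinuc	12	TA	0.7092612
dinuc	12	TC	0.496298609
dinuc	12	TT	-0.586873894
dinuc	13	GG	-0.334563735
dinuc	14	GA	0.76384993
dinuc	14	GC	-0.53702517
dinuc	17	TG	-0.798146133
dinuc	19	GG	-0.66680873
dinuc	19	TC	0.353183252
dinuc	20	CC	0.748072092
dinuc	20	TG	-0.367266772
dinuc	21	AC	0.568209132
dinuc	21	CG	0.329072074
dinuc	21	GA	-0.836456755
dinuc	21	GG	-0.782453512
dinuc	22	TC	-1.029692957
dinuc	23	CG	0.856197823
dinuc	23	CT	-0.463207679
dinuc	24	AA	-0.579492389
dinuc	24	AG	0.649075537
dinuc	25	AG	-0.077300704
dinuc	25	CG	0.287689025
dinuc	28	TG	-0.221304106
dinuc	29	CT	-0.689466786
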