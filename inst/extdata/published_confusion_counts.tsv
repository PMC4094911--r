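target_id	dataset	group	role	metric	ad_like	ctl_like
t1	training_baseline	AD	positive	sensitivity	100	19
t2	training_baseline	CTL	negative	specificity	10	100
t3	longitudinal_baseline	AD	positive	sensitivity	50	12
t4	longitudinal_baseline	CTL	negative	specificity	8	71
t5	longitudinal_baseline	MCI-c	positive	sensitivity	11	2
t6	longitudinal_baseline	MCI-nc	negative	specificity	21	39
t7	longitudinal_1year	AD	positive	sensitivity	57	5
t8	longitudinal_1year	CTL	negative	specificity	20	59
t9	longitudinal_1year	MCI-c	positive	sensitivity	12	1
t10	longitudinal_1year	MCI-nc	negative	specificity	32	28
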