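feature	block	paired	lobe	pop_mean	pop_sd	effect_ad_vs_ctl
bankssts	thickness	1	temporal	2.40	0.15	-0.40
caudal_anterior_cingulate	thickness	1	cingulate	2.60	0.20	-0.15
caudal_middle_frontal	thickness	1	frontal	2.50	0.15	-0.20
cuneus	thickness	1	occipital	1.80	0.12	-0.10
entorhinal	thickness	1	temporal	3.20	0.30	-1.40
fusiform	thickness	1	temporal	2.70	0.17	-1.10
inferior_parietal	thickness	1	parietal	2.40	0.15	-0.40
inferior_temporal	thickness	1	temporal	2.70	0.17	-1.05
isthmus_cingulate	thickness	1	cingulate	2.40	0.18	-0.35
lateral_occipital	thickness	1	occipital	2.10	0.13	-0.15
lateral_orbitofrontal	thickness	1	frontal	2.60	0.15	-0.20
lingual	thickness	1	occipital	1.90	0.12	-0.15
medial_orbitofrontal	thickness	1	frontal	2.40	0.15	-0.20
middle_temporal	thickness	1	temporal	2.80	0.17	-1.15
parahippocampal	thickness	1	temporal	2.70	0.25	-1.00
paracentral	thickness	1	frontal	2.40	0.15	-0.10
pars_opercularis	thickness	1	frontal	2.50	0.15	-0.20
pars_orbitalis	thickness	1	frontal	2.60	0.18	-0.20
pars_triangularis	thickness	1	frontal	2.40	0.15	-0.20
pericalcarine	thickness	1	occipital	1.60	0.12	-0.05
postcentral	thickness	1	parietal	2.00	0.13	-0.10
posterior_cingulate	thickness	1	cingulate	2.40	0.15	-0.35
precentral	thickness	1	frontal	2.50	0.15	-0.15
precuneus	thickness	1	parietal	2.30	0.14	-0.40
rostral_anterior_cingulate	thickness	1	cingulate	2.80	0.20	-0.15
rostral_middle_frontal	thickness	1	frontal	2.30	0.14	-0.20
superior_frontal	thickness	1	frontal	2.70	0.16	-0.25
superior_parietal	thickness	1	parietal	2.20	0.13	-0.25
superior_temporal	thickness	1	temporal	2.70	0.16	-1.25
supramarginal	thickness	1	parietal	2.50	0.15	-0.30
frontal_pole	thickness	1	frontal	2.70	0.22	-0.20
temporal_pole	thickness	1	temporal	3.60	0.30	-1.30
transverse_temporal	thickness	1	temporal	2.30	0.20	-0.20
insula	thickness	1	insula	3.00	0.18	-0.25
third_ventricle	volume	0	ventricular	1100	400	0.35
fourth_ventricle	volume	0	ventricular	1800	600	0.05
brainstem	volume	0	midline	20000	2200	-0.05
cc_anterior	volume	0	midline	900	150	-0.15
cc_central	volume	0	midline	450	110	-0.10
cc_mid_anterior	volume	0	midline	450	110	-0.10
cc_mid_posterior	volume	0	midline	450	100	-0.10
cc_posterior	volume	0	midline	950	160	-0.15
csf	volume	0	ventricular	1000	300	0.25
accumbens	volume	1	subcortical	550	100	-0.25
amygdala	volume	1	subcortical	1500	220	-1.35
caudate	volume	1	subcortical	3500	450	-0.10
cerebellum_cortex	volume	1	cerebellum	52000	5500	-0.10
cerebellum_white_matter	volume	1	cerebellum	14000	2200	-0.10
hippocampus	volume	1	subcortical	3900	500	-1.50
inferior_lateral_ventricle	volume	1	ventricular	900	550	1.20
putamen	volume	1	subcortical	4800	600	-0.15
cerebral_cortex	volume	1	global	230000	22000	-0.35
cerebral_white_matter	volume	1	global	220000	25000	-0.25
lateral_ventricle	volume	1	ventricular	18000	9000	0.45
pallidum	volume	1	subcortical	1600	250	-0.10
thalamus_proper	volume	1	subcortical	6500	750	-0.20
ventral_dc	volume	1	subcortical	3700	450	-0.15
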