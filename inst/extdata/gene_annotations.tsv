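gene	n_cases	flags	plof_oe	plof_oe_ci
FAT3	32	Yes	0.18	0.13-0.25
SYNE1	31	Yes	0.37	0.33-0.42
FAT1	29	Yes	0.34	0.27-0.43
ATM	25	No	0.6	0.51-0.71
BIRC6	24	No	0.07	0.04-0.1
CLTCL1	24	No	0.8	0.66-0.98
ZFHX3	23	Yes	0.08	0.05-0.14
TSC2	22	No	0.02	0.01-0.07
MYH9	20	No	0.04	0.02-0.09
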