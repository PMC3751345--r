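#map chr26 salmon cM
#id salmon_chr26_published
#title published salmon linkage map chr26
#extent 0 58.2
SSA26_001	8.1	8.1	.	variant	ARKSNP0001
SSA26_002	17.2	17.2	.	variant	ARKSNP0002
SSA26_003	27.5	27.5	.	variant	ARKSNP0003
SSA26_004	31.1	31.1	.	variant	ARKSNP0004
SSA26_005	38.5	38.5	.	variant	ARKSNP0005
SSA26_006	39.4	39.4	.	variant	ARKSNP0006
SSA26_007	42.3	42.3	.	variant	ARKSNP0007
SSA26_008	43.1	43.1	.	variant	ARKSNP0008
SSA26_009	44.2	44.2	.	variant	ARKSNP0009
SSA26_010	49.8	49.8	.	variant	ARKSNP0010
SSA26_011	54.9	54.9	.	variant	ARKSNP0011
SSA26_012	56.2	56.2	.	variant	ARKSNP0012
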