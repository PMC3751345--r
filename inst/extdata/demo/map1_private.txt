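#map chr26 salmon cM
#id salmon_qtl_private
#title private salmon QTL map
#extent 0 58.2
SSA26_004	31.1	31.1	.	variant	ARKSNP0004
SSA26_005	39	39	.	variant	ARKSNP0005
SSA26_006	40.3	40.3	.	variant	ARKSNP0006
SSA26_007	41.7	41.7	.	variant	ARKSNP0007
QTL1	41.8	41.8	.	generic
SSA26_009	44.1	44.1	.	variant	ARKSNP0009
SSA26_011	54.8	54.8	.	variant	ARKSNP0011
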