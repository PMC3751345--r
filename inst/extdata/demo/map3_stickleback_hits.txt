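#map groupIV stickleback bp
#id stickleback_grpIV_hits
#title stickleback groupIV sequence hits
#extent 1 4000000
#assembly gacAsm1
SSA26_001	214214	214214	.	sequence	GACHIT001
SSA26_003	1597190	1597190	.	sequence	GACHIT003
SSA26_005	2666611	2666611	.	sequence	GACHIT005
SSA26_007	2855344	2855344	.	sequence	GACHIT007
SSA26_009	3119799	3119799	.	sequence	GACHIT009
SSA26_011	3198498	3198498	.	sequence	GACHIT011
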