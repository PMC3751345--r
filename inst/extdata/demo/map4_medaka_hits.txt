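#map chr12 medaka bp
#id medaka_chr12_hits
#title medaka chr12 sequence hits
#extent 1 4000000
#assembly olaAsm1
SSA26_002	226403	226403	.	sequence	OLAHIT002
SSA26_004	947572	947572	.	sequence	OLAHIT004
SSA26_006	1566413	1566413	.	sequence	OLAHIT006
SSA26_008	1768778	1768778	.	sequence	OLAHIT008
SSA26_010	2402403	2402403	.	sequence	OLAHIT010
SSA26_012	3463765	3463765	.	sequence	OLAHIT012
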