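#map chr12 medaka bp
#id medaka_chr12_asm
#title medaka annotated assembly
#extent 1 4000000
#assembly olaAsm1
medaka_g01	8966	64875	-	gene	ENSORLG0001
SSA26_002	226403	226403	.	sequence	OLAHIT002
SSA26_004	947572	947572	.	sequence	OLAHIT004
medaka_g02	1408774	1447827	-	gene	ENSORLG0002
medaka_g03	1552004	1561712	+	gene	ENSORLG0003
SSA26_006	1566413	1566413	.	sequence	OLAHIT006
medaka_g04	1635583	1652526	+	gene	ENSORLG0004
SSA26_008	1768778	1768778	.	sequence	OLAHIT008
medaka_g05	1790138	1836056	-	gene	ENSORLG0005
medaka_g06	2112873	2169189	+	gene	ENSORLG0006
medaka_g07	2284206	2301116	+	gene	ENSORLG0007
SSA26_010	2402403	2402403	.	sequence	OLAHIT010
medaka_g08	2408120	2453494	+	gene	ENSORLG0008
medaka_g09	2920907	2937377	-	gene	ENSORLG0009
medaka_g10	2955712	2960724	+	gene	ENSORLG0010
medaka_g11	2981044	3014371	+	gene	ENSORLG0011
medaka_g12	3283073	3322515	-	gene	ENSORLG0012
medaka_g13	3327693	3351011	-	gene	ENSORLG0013
SSA26_012	3463765	3463765	.	sequence	OLAHIT012
medaka_g14	3749290	3771076	-	gene	ENSORLG0014
medaka_g15	3810284	3851991	+	gene	ENSORLG0015
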