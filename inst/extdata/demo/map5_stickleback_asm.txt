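#map groupIV stickleback bp
#id stickleback_grpIV_asm
#title stickleback annotated assembly
#extent 1 4000000
#assembly gacAsm1
stickleback_g01	171649	178790	-	gene	ENSGACG0001
SSA26_001	214214	214214	.	sequence	GACHIT001
stickleback_g02	555429	601612	-	gene	ENSGACG0002
stickleback_g03	683849	690907	-	gene	ENSGACG0003
stickleback_g04	753475	776812	+	gene	ENSGACG0004
stickleback_g05	856400	898649	+	gene	ENSGACG0005
stickleback_g06	950596	998753	+	gene	ENSGACG0006
stickleback_g07	1029067	1087611	+	gene	ENSGACG0007
SSA26_003	1597190	1597190	.	sequence	GACHIT003
stickleback_g08	2042865	2071610	-	gene	ENSGACG0008
stickleback_g09	2232870	2291272	+	gene	ENSGACG0009
stickleback_g10	2663469	2721135	-	gene	ENSGACG0010
SSA26_005	2666611	2666611	.	sequence	GACHIT005
stickleback_g11	2754161	2781077	+	gene	ENSGACG0011
SSA26_007	2855344	2855344	.	sequence	GACHIT007
stickleback_g12	3007644	3047842	+	gene	ENSGACG0012
SSA26_009	3119799	3119799	.	sequence	GACHIT009
SSA26_011	3198498	3198498	.	sequence	GACHIT011
stickleback_g13	3292700	3316770	-	gene	ENSGACG0013
stickleback_g14	3365591	3404626	-	gene	ENSGACG0014
stickleback_g15	3878367	3932193	+	gene	ENSGACG0015
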