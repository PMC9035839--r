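family	id	smiles
gallate	gallate01	COC(=O)c1cc(O)c(O)c(O)c1
gallate	gallate02	CCOC(=O)c1cc(O)c(O)c(O)c1
gallate	gallate03	CCCOC(=O)c1cc(O)c(O)c(O)c1
gallate	gallate04	CCCCOC(=O)c1cc(O)c(O)c(O)c1
gallate	gallate05	CCCCCOC(=O)c1cc(O)c(O)c(O)c1
gallate	gallate06	CCCCCCOC(=O)c1cc(O)c(O)c(O)c1
gallate	gallate07	CCCCCCCOC(=O)c1cc(O)c(O)c(O)c1
gallate	gallate08	CCCCCCCCOC(=O)c1cc(O)c(O)c(O)c1
gallate	gallate09	CCCCCCCCCOC(=O)c1cc(O)c(O)c(O)c1
gallate	gallate10	CCCCCCCCCCOC(=O)c1cc(O)c(O)c(O)c1
paraben	paraben01	COC(=O)c1ccc(O)cc1
paraben	paraben02	CCOC(=O)c1ccc(O)cc1
paraben	paraben03	CCCOC(=O)c1ccc(O)cc1
paraben	paraben04	CCCCOC(=O)c1ccc(O)cc1
paraben	paraben05	CCCCCOC(=O)c1ccc(O)cc1
paraben	paraben06	CCCCCCOC(=O)c1ccc(O)cc1
paraben	paraben07	CCCCCCCOC(=O)c1ccc(O)cc1
paraben	paraben08	CCCCCCCCOC(=O)c1ccc(O)cc1
paraben	paraben09	CCCCCCCCCOC(=O)c1ccc(O)cc1
paraben	paraben10	CCCCCCCCCCOC(=O)c1ccc(O)cc1
benzamide	benzamide01	O=C(NC)c1ccccc1
benzamide	benzamide02	O=C(NCC)c1ccccc1
benzamide	benzamide03	O=C(NCCC)c1ccccc1
benzamide	benzamide04	O=C(NCCCC)c1ccccc1
benzamide	benzamide05	O=C(NCCCCC)c1ccccc1
benzamide	benzamide06	O=C(NCCCCCC)c1ccccc1
benzamide	benzamide07	O=C(NCCCCCCC)c1ccccc1
benzamide	benzamide08	O=C(NCCCCCCCC)c1ccccc1
benzamide	benzamide09	O=C(NCCCCCCCCC)c1ccccc1
benzamide	benzamide10	O=C(NCCCCCCCCCC)c1ccccc1
aniline	aniline01	Cc1ccc(N)cc1
aniline	aniline02	CCc1ccc(N)cc1
aniline	aniline03	CCCc1ccc(N)cc1
aniline	aniline04	CCCCc1ccc(N)cc1
aniline	aniline05	CCCCCc1ccc(N)cc1
aniline	aniline06	CCCCCCc1ccc(N)cc1
aniline	aniline07	CCCCCCCc1ccc(N)cc1
aniline	aniline08	CCCCCCCCc1ccc(N)cc1
aniline	aniline09	CCCCCCCCCc1ccc(N)cc1
aniline	aniline10	CCCCCCCCCCc1ccc(N)cc1
fattyacid	fattyacid02	CCC(=O)O
fattyacid	fattyacid03	CCCC(=O)O
fattyacid	fattyacid04	CCCCC(=O)O
fattyacid	fattyacid05	CCCCCC(=O)O
fattyacid	fattyacid06	CCCCCCC(=O)O
fattyacid	fattyacid07	CCCCCCCC(=O)O
fattyacid	fattyacid08	CCCCCCCCC(=O)O
fattyacid	fattyacid09	CCCCCCCCCC(=O)O
fattyacid	fattyacid10	CCCCCCCCCCC(=O)O
fattyacid	fattyacid11	CCCCCCCCCCCC(=O)O
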