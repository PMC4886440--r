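name	pattern	family	source
ACGTABREMOTIFA2OSEM	ACGTGKC	ABRE/bZIP	PLACE
CACGTGMOTIF	CACGTG	bHLH/bZIP	PLACE
CCA1-1	AGATATTT	MYB-related	PBM
ABREATCONSENSUS	YACGTGGC	ABRE/bZIP	PLACE
IRO2OS	CACGTGG	bHLH/bZIP	PLACE
MYC2-5	CACGCG	bHLH	PBM
ABRERATCAL	MACGYGB	ABRE/bZIP	PLACE
SORLIP1AT	GCCAC	Light	PLACE
E2FCONSENSUS	WTTSSCSS	E2F	PLACE
SORLIP5AT	GAGTGAG	Light	PLACE
WBOXNTCHN48	CTGACY	WRKY	PLACE
ETT-1	TGTCGG	ARF	PBM
DRE2COREZMRAB17	ACCGAC	AP2/ERF	PLACE
DRECRTCOREAT	RCCGAC	AP2/ERF	PLACE
CBFHV	RYCGACC	AP2/ERF	PLACE
MYBPZM	CCWACC	MYB	PLACE
BOXLCOREDCPAL	ACCWWCC	MYB	PLACE
ETT-2	TGTCGA	ARF	PBM
TCP15	GGNCCCAC	TCP	PBM
RAP2.3-3	GCCGAC	AP2/ERF	PBM
CATGTGMOTIF	CATGTG	bHLH/NAC	text
CARGCW8GAT	CWWWWWWWWG	MADS	text
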