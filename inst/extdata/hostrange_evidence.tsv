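# Curated receptor-dependency and recipient-efficiency evidence per TraN
# class. Tiers are qualitative (high / reduced / very_low / untested)
# because per-pair conjugation frequencies are reported graphically only;
# printed magnitudes (~80-fold, ~350-fold) are kept inside the evidence
# strings. receptor "unknown" is explicit. Greek letters spelled out.
tran_class	family	receptor	recipient	tier	evidence
TraN_Malpha	M	unknown	Citrobacter freundii	high	Fig 5A: RA1 conjugated efficiently into C. freundii
TraN_Malpha	M	unknown	Shigella sonnei	high	Fig 5A: RA1 conjugated efficiently into S. sonnei
TraN_Malpha	M	unknown	Escherichia coli MG1655	high	Fig 5A: RA1 conjugated efficiently into MG1655
TraN_Malpha	M	unknown	Klebsiella pneumoniae	reduced	Fig 5A: ~80-fold lower efficiency into K. pneumoniae
TraN_Malpha	M	unknown	Enterobacter cloacae	reduced	Fig 5A: ~80-fold lower efficiency into E. cloacae
TraN_Malpha	M	unknown	Salmonella Enteritidis	reduced	Fig 5A: ~80-fold lower efficiency into S. Enteritidis
TraN_Malpha	M	unknown	enteropathogenic E. coli (EPEC)	very_low	Fig 5A: very low frequency into EPEC E2348/69
TraN_Malpha	M	unknown	-	note	Fig 8B: RA1 (TraN_M tip) conjugation OmpA-independent; Discussion: partner OMP of TraN_M unknown; Fig 5C: tip-less RA1 ~350-fold lower into MG1655
TraN_Mbeta	M	unknown	Citrobacter freundii	high	Fig 6B: TraN_Mbeta tip mediates efficiency similar to TraN_Malpha
TraN_Mbeta	M	unknown	Shigella sonnei	high	Fig 6B: similar to TraN_Malpha
TraN_Mbeta	M	unknown	Escherichia coli MG1655	high	Fig 6B: similar to TraN_Malpha
TraN_Mbeta	M	unknown	Klebsiella pneumoniae	reduced	Fig 6B: similar to TraN_Malpha
TraN_Mbeta	M	unknown	Enterobacter cloacae	reduced	Fig 6B: similar to TraN_Malpha
TraN_Mbeta	M	unknown	Salmonella Enteritidis	reduced	Fig 6B: subtle decrease into S. Enteritidis vs TraN_Malpha
TraN_Mbeta	M	unknown	enteropathogenic E. coli (EPEC)	very_low	Fig 6B: similar to TraN_Malpha
TraN_Lalpha	L	OmpA	Klebsiella pneumoniae	high	Fig 5B: R27 conjugated with high frequency into K. pneumoniae
TraN_Lalpha	L	OmpA	enteropathogenic E. coli (EPEC)	high	Fig 5B: R27 conjugated with high frequency into EPEC
TraN_Lalpha	L	OmpA	Escherichia coli MG1655	high	Fig 5B: R27 conjugated with high frequency into MG1655
TraN_Lalpha	L	OmpA	Enterobacter cloacae	reduced	Fig 5B: lower frequency into E. cloacae
TraN_Lalpha	L	OmpA	Shigella sonnei	reduced	Fig 5B: lower frequency into S. sonnei
TraN_Lalpha	L	OmpA	Salmonella Enteritidis	very_low	Fig 5B: frequency dropped significantly into S. Enteritidis
TraN_Lalpha	L	OmpA	Citrobacter freundii	very_low	Fig 5B: frequency dropped significantly into C. freundii
TraN_Lalpha	L	OmpA	-	note	Fig 8A: R27 conjugated at lower frequency specifically into a delta-ompA recipient; Fig 5D: tip-less R27 ~350-fold lower into MG1655
TraN_Lbeta	L	OmpA	-	untested	Discussion: TraN_L variants share similar structure and use OmpA as recipient partner; TraN_Lbeta recipient panel not assayed
TraN_Lgamma	L	OmpA	Klebsiella pneumoniae	high	Fig 6C: unchanged vs TraN_Lalpha (high)
TraN_Lgamma	L	OmpA	enteropathogenic E. coli (EPEC)	high	Fig 6C: unchanged vs TraN_Lalpha (high)
TraN_Lgamma	L	OmpA	Escherichia coli MG1655	high	Fig 6C: unchanged vs TraN_Lalpha (high)
TraN_Lgamma	L	OmpA	Shigella sonnei	reduced	Fig 6C: unchanged vs TraN_Lalpha (reduced)
TraN_Lgamma	L	OmpA	Salmonella Enteritidis	reduced	Fig 6C: higher frequency into S. Enteritidis than TraN_Lalpha
TraN_Lgamma	L	OmpA	Enterobacter cloacae	very_low	Fig 6C: lower efficiency specifically into E. cloacae vs TraN_Lalpha
TraN_Lgamma	L	OmpA	Citrobacter freundii	very_low	Fig 6C: unchanged vs TraN_Lalpha (very low)
TraN_Lgamma	L	OmpA	-	note	Fig 8D: TraN_Lgamma on the R27 base maintained OmpA dependency
TraN_V	V	unknown	Escherichia coli MG1655	high	Fig 7D: R27::TraN_V conjugated with high efficiency into MG1655
TraN_V	V	unknown	enteropathogenic E. coli (EPEC)	high	Fig 7D: high efficiency into EPEC
TraN_V	V	unknown	Klebsiella pneumoniae	high	Fig 7D: high efficiency into K. pneumoniae
TraN_V	V	unknown	Acinetobacter baumannii	high	Fig 7C: TraN_V, T1 and T2 all conjugate into A. baumannii above R27 and tip-less R27
TraN_V	V	unknown	Citrobacter freundii	very_low	Fig 7D: much lower efficiency into C. freundii
TraN_V	V	unknown	Enterobacter cloacae	very_low	Fig 7D: much lower efficiency into E. cloacae
TraN_V	V	unknown	Shigella sonnei	very_low	Fig 7D: much lower efficiency into S. sonnei
TraN_V	V	unknown	Salmonella Enteritidis	very_low	Fig 7D: much lower efficiency into S. Enteritidis
TraN_V	V	unknown	-	note	Fig 7B/C: tip T2 functions only toward A. baumannii (R27::TraN_V-T2 was not conjugated into MG1655); Fig 8C: TraN_V conjugation OmpA-independent
TraN_Salpha	S	OmpW	-	untested	Introduction: TraN_S alpha isotype pairs specifically with OmpW; recipient panel from prior IncF work
TraN_Sbeta	S	OmpK36	-	untested	Introduction: TraN_S beta isotype pairs specifically with OmpK36; mainly found in Klebsiella
TraN_Sgamma	S	OmpA	-	untested	Introduction: TraN_S gamma isotype pairs specifically with OmpA; mainly found in E. coli
TraN_Sdelta	S	OmpF	-	untested	Introduction: TraN_S delta isotype pairs specifically with OmpF
TraN_S	S	unknown	-	untested	Family-level entry: receptor depends on the TraN_S isotype (OmpW/OmpK36/OmpA/OmpF); subtype with user-supplied TraN_S profiles
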