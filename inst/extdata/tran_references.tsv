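# TraN subclade reference profiles: representative protein per subclade,
# deposited length and receptor-binding tip span with anchor residues
# (tip_start/tip_end are 1-based positions on the full deposited protein).
# Greek subclade letters are spelled out (Malpha = M-alpha, etc.).
name	protein_id	source_plasmid	family	length	tip_start	tip_end	anchor_start	anchor_end
TraN_Malpha	ACN66968.1	RA1	M	912	230	360	C	D
TraN_Mbeta	AHI38890.1	pNDM-US	M	932	205	354	N	V
TraN_Lalpha	AAF69844.1	R27	L	1058	305	457	S	E
TraN_Lbeta	APZ78090.1	pHNAH67	L	1062	305	457	T	E
TraN_Lgamma	AFB82831.1	pNDM-MAR	L	1061	304	457	S	D
TraN_V	QBN23304.1	pABAY10001	V	891	149	628	V	R
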