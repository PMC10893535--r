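annotation	locus_tag	length_bp	occurrence_count	product
Biofilm-related genes	RS16150	279	1	Veg family protein
Biofilm-related genes	RS07500	669	1	PilZ domain-containing protein
Cell wall-related genes	RS17880	663	1	M23 family metallopeptidase
Cell wall-related genes	RS05630	1098	1	polysaccharide pyruvyl transferase CsaB
Cell wall-related genes	RS02655	1101	1	D-alanine--D-alanine ligase
Cell wall-related genes	RS16455	1275	1	UDP-N-acetylglucosamine 1-carboxyvinyltransferase
Cell wall-related genes	RS13520	1506	1	UDP-N-acetylmuramoyl-L-alanyl-D-glutamate--2,6-diaminopimelate ligase
Membrane proteins	RS08320	768	1	ABC transporter permease
Membrane proteins	RS09880	1032	1	ABC transporter substrate-binding protein
Membrane proteins	RS07025	1095	1	YeeE/YedE family protein
Membrane proteins	RS12640	1797	1	ATP-dependent zinc metalloprotease FtsH
Metabolism	RS06785	636	1	guanylate kinase
Metabolism	RS00715	813	1	NAD(P) binding domain-containing protein
Metabolism	RS14505	1461	1	IMP dehydrogenase
Transcription and translation	RS16105	570	1	aminoacyl-tRNA hydrolase
Transcription and translation	RS17470	624	1	helix-turn-helix transcriptional regulator
Transcription and translation	RS09835	702	1	RNA polymerase sporulation sigma factor SigK
Transcription and translation	RS16160	858	1	16S rRNA (adenine(1518)-N(6)/adenine(1519)-N(6))-dimethyltransferase RsmA
Transcription and translation	RS05755	1227	1	tyrosine--tRNA ligase
Transcription and translation	RS12140	2562	1	single-stranded-DNA-specific exonuclease RecJ
Stress response	RS07085	507	1	Hsp20/alpha crystallin family protein
DNA recombinant	RS09165	885	1	site-specific tyrosine recombinase XerD
Polysaccharides degradation	RS02780	1293	1	glycoside hydrolase family 18 protein
Unknown function	RS18735	210	1	hypothetical protein
Unknown function	RS11335	246	1	hypothetical protein
Unknown function	RS09245	447	1	hypothetical protein
Unknown function	RS18275	558	1	hypothetical protein
Unknown function	RS14425	666	1	hypothetical protein
Unknown function	RS18470	672	1	hypothetical protein
Unknown function	RS06565	921	1	hypothetical protein
Unknown function	RS01700	921	1	hypothetical protein
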