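# SYNTHETIC bioactive-peptide source database for bovine beta-casein,
# emulating entries of the style found in BIOPEP, MBPDB and EROP-Moscow.
# One row per (peptide, source). Fragment coordinates are 1-based on the
# 224-residue P02666 precursor. Evidence flags encode the curation rules:
# has_reference (rule i), predicted_only (ii), sequence_discrepancy (iii),
# bitter_only (iv). Activities use the controlled vocabulary
# ACE-I, DPP-IV-I, Immuno, AntiM, AntiO, PEP-I, Opioid, other:<text>.
sequence	parent	fragment_start	fragment_end	activities	references	source	has_reference	predicted_only	sequence_discrepancy	bitter_only
YPFPGPIPN	P02666	75	83	ACE-I;DPP-IV-I;Opioid	r56;r57;r58	MBPDB-like	TRUE	FALSE	FALSE	FALSE
YPFPGPIPN	P02666	75	83	Opioid	r56	EROP-like	TRUE	FALSE	FALSE	FALSE
LPQNIPP	P02666	85	91	DPP-IV-I	r57	MBPDB-like	TRUE	FALSE	FALSE	FALSE
LPQNIPPL	P02666	85	92	DPP-IV-I	r57	MBPDB-like	TRUE	FALSE	FALSE	FALSE
TQTPVVVPPFLQPE	P02666	93	106	AntiO	r59	BIOPEP-like	TRUE	FALSE	FALSE	FALSE
HKEMPFPK	P02666	121	128	AntiM	r60	BIOPEP-like	TRUE	FALSE	FALSE	FALSE
YPVEPFTE	P02666	129	136	ACE-I	r61	BIOPEP-like	TRUE	FALSE	FALSE	FALSE
SQSKVLPVPQ	P02666	181	190	ACE-I	r9	MBPDB-like	TRUE	FALSE	FALSE	FALSE
RDMPIQAF	P02666	198	205	ACE-I	r40	EROP-like	TRUE	FALSE	FALSE	FALSE
QEPVLGPVRGPFPIIV	P02666	209	224	ACE-I	r62	BIOPEP-like	TRUE	FALSE	FALSE	FALSE
QEPVLGPVRGPFPIIV	P02666	209	224	ACE-I	r62	MBPDB-like	TRUE	FALSE	FALSE	FALSE
LNVPGEIVE	P02666	21	29	ACE-I	r10	MBPDB-like	TRUE	FALSE	FALSE	FALSE
VYPFPGPIPN	P02666	74	83	ACE-I;AntiO	r63	MBPDB-like	TRUE	FALSE	FALSE	FALSE
LVYPFPGPIPNSLPQ	P02666	73	87	ACE-I;PEP-I	r64	BIOPEP-like	TRUE	FALSE	FALSE	FALSE
PQNIPPL	P02666	86	92	DPP-IV-I	r57	MBPDB-like	TRUE	FALSE	FALSE	FALSE
NIPPLTQTPV	P02666	88	97	ACE-I	r10	MBPDB-like	TRUE	FALSE	FALSE	FALSE
VKEAMAPK	P02666	113	120	AntiO;AntiM	r65	EROP-like	TRUE	FALSE	FALSE	FALSE
LHLPLPL	P02666	148	154	ACE-I	r11	MBPDB-like	TRUE	FALSE	FALSE	FALSE
NLHLPLPLL	P02666	147	155	ACE-I	r66	BIOPEP-like	TRUE	FALSE	FALSE	FALSE
KVLPVPQK	P02666	184	191	AntiO	r65	EROP-like	TRUE	FALSE	FALSE	FALSE
KVLPVPQ	P02666	184	190	ACE-I	r67	BIOPEP-like	TRUE	FALSE	FALSE	FALSE
KVLPVPQ	P02666	184	190	ACE-I	r67	EROP-like	TRUE	FALSE	FALSE	FALSE
VLPVPQK	P02666	185	191	AntiM;AntiO	r65	EROP-like	TRUE	FALSE	FALSE	FALSE
YQEPVLGPVRGPFPIIV	P02666	208	224	ACE-I;AntiM;Immuno	r68;r69;r70	MBPDB-like	TRUE	FALSE	FALSE	FALSE
AVPYPQR	P02666	192	198	ACE-I;AntiM;AntiO	r60;r65;r71	MBPDB-like	TRUE	FALSE	FALSE	FALSE
YPFPGPI	P02666	75	81	Opioid	NA	BIOPEP-like	FALSE	FALSE	FALSE	FALSE
YPFPGPI	P02666	75	81	Opioid	r35	EROP-like	TRUE	FALSE	FALSE	FALSE
YPFPGPI	P02666	75	81	Opioid;ACE-I;other:satiety	r35;r36;r6	MBPDB-like	TRUE	FALSE	FALSE	FALSE
SLPQNIPPLTQTPVVVPP	P02666	84	101	ACE-I	NA	BIOPEP-like	FALSE	FALSE	FALSE	FALSE
GPVRGPFP	P02666	214	221	DPP-IV-I	r72	BIOPEP-like	TRUE	TRUE	FALSE	FALSE
MHQPHQPLPPT	P02666	159	169	ACE-I	r73	EROP-like	TRUE	FALSE	TRUE	FALSE
GPFPIIV	P02666	218	224	other:bitter	r41	BIOPEP-like	TRUE	FALSE	FALSE	TRUE
YPVEPF	P02666	129	134	other:bitter	r41	EROP-like	TRUE	FALSE	FALSE	TRUE
PPFLQPE	P02666	100	106	AntiO	r74	MBPDB-like	TRUE	TRUE	FALSE	FALSE
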