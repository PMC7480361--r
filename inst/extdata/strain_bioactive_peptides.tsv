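# Beta-casein-derived bioactive peptides identified in the intracellular
# peptidomes of L. lactis MG1363 and six isogenic peptidase deletion strains,
# transcribed from the published survey (values exactly as printed, including
# two typographical fragment coordinates; mass errors per biological
# replicate, ND = not detected in that replicate). MGdpepVDATDB yielded none.
strain	sequence	fragment_start	fragment_end	theoretical_mass	mass_error_ppm	activities	references
MG1363	YPFPGPIPN	75	83	1000.5018	0.9/3.4/-1.8	ACE-I;DPP-IV-I;Opioid	r56;r57;r58
MG1363	LPQNIPP	85	91	777.4385	3.3/4.9/3.6	DPP-IV-I	r57
MG1363	LPQNIPPL	85	92	890.5225	3.1/ND/-0.5	DPP-IV-I	r57
MG1363	TQTPVVVPPFLQPE	9	106	1550.8344	3.6/6.8/ND	AntiO	r59
MGdpepOF2O2	YPFPGPIPN	75	83	1000.5018	3.3/2.8/0	ACE-I;DPP-IV-I;Opioid	r56;r57;r58
MGdpepOF2O2	HKEMPFPK	121	128	1012.5164	0.3/-2/-1.3	AntiM	r60
MGdpepOF2O2	YPVEPFTE	129	136	980.4491	9.7/8/4.3	ACE-I	r61
MGdpepOF2O2	SQSKVLPVPQ	181	190	1081.6132	6.7/6.9/5.4	ACE-I	r9
MGdpepOF2O2	RDMPIQAF	198	205	976.4800	ND/6.1/5	ACE-I	r40
MGdpepOF2O2	QEPVLGPVRGPFPIIV	209	224	1716.9926	4.8/6.1/2.5	ACE-I	r62
MGdpepNXOTCF2O2	LNVPGEIVE	21	29	968.5178	2.5/3.8/2.5	ACE-I	r10
MGdpepNXOTCF2O2	VYPFPGPIPN	74	83	1099.5702	1.3/2/3.2	ACE-I;AntiO	r63
MGdpepNXOTCF2O2	LVYPFPGPIPNSLPQ	73	87	1637.8817	3.6/3.8/ND	ACE-I;PEP-I	r64
MGdpepNXOTCF2O2	LPQNIPPL	85	92	890.5225	2.8/1.5/4	DPP-IV-I	r57
MGdpepNXOTCF2O2	PQNIPPL	86	92	777.4385	2.9/2/2.2	DPP-IV-I	r57
MGdpepNXOTCF2O2	NIPPLTQTPV	88	97	1078.6023	4.2/4.6/4.6	ACE-I	r10
MGdpepNXOTCF2O2	TQTPVVVPPFLQPE	93	106	1550.8344	2.5/2.5/2.5	AntiO	r59
MGdpepNXOTCF2O2	VKEAMAPK	113	120	872.4789	-2.9/-4.1/-1.6	AntiO;AntiM	r65
MGdpepNXOTCF2O2	HKEMPFPK	121	128	1012.5164	5.2/2.9/4.1	AntiM	r60
MGdpepNXOTCF2O2	LHLPLPL	148	154	801.5112	2.8/5.5/6.1	ACE-I	r11
MGdpepNXOTCF2O2	NLHLPLPLL	147	155	1028.6382	1.9/3.8/3.9	ACE-I	r66
MGdpepNXOTCF2O2	SQSKVLPVPQ	181	190	1081.6132	3.8/5.1/4.5	ACE-I	r9
MGdpepNXOTCF2O2	KVLPVPQK	184	191	907.5854	5.1/4.5/7	AntiO	r65
MGdpepNXOTCF2O2	KVLPVPQ	184	190	779.4905	3.6/1.8/9.1	ACE-I	r67
MGdpepNXOTCF2O2	VLPVPQK	185	191	779.4905	4.7/6.9/7.6	AntiM;AntiO	r65
MGdpepNXOTCF2O2	RDMPIQAF	198	205	976.4800	4.7/3.8/4.9	ACE-I	r40
MGdpepNXOTCF2O2	YQEPVLGPVRGPFPIIV	208	224	1880.0559	4.3/4.3/ND	ACE-I;AntiM;Immuno	r68;r69;r70
MGdpepNXOTCF2O2	QEPVLGPVRGPFPIIV	209	224	1716.9926	2.6/2.7/2.2	ACE-I	r62
MGdpepXPQ	YPFPGPIPN	85	83	1000.5018	-0.6/-1.4/-0.3	ACE-I;DPP-IV-I;Opioid	r56;r57;r58
MGdpepXPQ	LPQNIPPL	85	92	890.5225	1.5/2.8/ND	DPP-IV-I	r57
MGdpepNXOTCVDA	LNVPGEIVE	21	29	968.5178	ND/1.9/2	ACE-I	r10
MGdpepNXOTCVDA	VYPFPGPIPN	74	83	1099.5702	ND/2.5/3.4	ACE-I;AntiO	r63
MGdpepNXOTCVDA	LPQNIPPL	85	92	890.5225	ND/3.9/4.9	DPP-IV-I	r57
MGdpepNXOTCVDA	PQNIPPL	86	92	777.4385	ND/1.7/4.1	DPP-IV-I	r57
MGdpepNXOTCVDA	NIPPLTQTPV	88	97	1078.6023	ND/3.9/5.5	ACE-I	r10
MGdpepNXOTCVDA	TQTPVVVPPFLQPE	93	106	1550.8344	ND/3.6/4.7	AntiO	r59
MGdpepNXOTCVDA	LHLPLPL	148	154	801.5112	ND/5.8/3.5	ACE-I	r11
MGdpepNXOTCVDA	SQSKVLPVPQ	181	190	1081.6132	ND/4.5/4.3	ACE-I	r9
MGdpepNXOTCVDA	KVLPVPQ	184	190	779.4905	1.4/0.8/2.9	ACE-I	r67
MGdpepANCpcp	LNVPGEIVE	21	29	968.5178	2.9/6.4/4.2	ACE-I	r10
MGdpepANCpcp	VYPFPGPIPN	74	83	1099.5702	5.4/5.5/4.8	ACE-I;AntiO	r63
MGdpepANCpcp	NIPPLTQTPV	88	97	1078.6023	4.7/8/10	ACE-I	r10
MGdpepANCpcp	TQTPVVVPPFLQPE	93	106	1550.8344	6.2/8.2/6.7	AntiO	r59
MGdpepANCpcp	HKEMPFPK	121	128	1012.5164	0.1/1.2/-0.1	AntiM	r60
MGdpepANCpcp	LHLPLPL	148	154	801.5112	5.2/9.4/6.7	ACE-I	r11
MGdpepANCpcp	SQSKVLPVPQ	181	190	1081.6132	4.7/4.9/6.5	ACE-I	r9
MGdpepANCpcp	KVLPVPQ	184	190	779.4905	4.1/1.8/3.9	ACE-I	r67
MGdpepANCpcp	AVPYPQR	192	198	829.4446	2.9/1.4/ND	ACE-I;AntiM;AntiO	r60;r65;r71
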