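tf_class	pattern	source_label	is_paper_sourced
CREB	TGACGTCA	Vance & Goding 2004, MITF promoter CRE	TRUE
FOXD3	RTAAAYA	forkhead-core placeholder; no binding sequence in the compiled motif table	FALSE
LEF1	CTTTGAT	Vance & Goding 2004, MITF promoter	TRUE
LEF1	CTTTGGGTCATGTG	Schwahn et al. 2005, LEF-1 & M-box	TRUE
MITF	CATGTG	Bentley et al. 1994 / Fuse et al. 1996, M-box core	TRUE
MITF	CACGTG	Loftus et al. 2009, E-box motif	TRUE
MITF	CANNTG	Murisier et al. 2006, E-box consensus	TRUE
MITF	AGTCANNTGCT	Murisier et al. 2007, M-box	TRUE
MITF	AGTCATGTGCT	Vachtenheim & Borovansky 2010	TRUE
MITF	ACATGTGA	Vachtenheim & Borovansky 2010	TRUE
MITF	AATCATGTGCT	Vachtenheim & Borovansky 2010	TRUE
MITF	GGTCATGTGCT	Vachtenheim & Borovansky 2010	TRUE
MITF	GCACATGAGT	Vachtenheim & Borovansky 2010	TRUE
MITF	GCTCACATGCT	Vachtenheim & Borovansky 2010	TRUE
MITF	TCACGTGTG	Vachtenheim & Borovansky 2010	TRUE
MITF	TCACATGAA	Vachtenheim & Borovansky 2010	TRUE
MITF	GGCACATGATG	Vachtenheim & Borovansky 2010	TRUE
MITF	ACAGCTGA	Vachtenheim & Borovansky 2010	TRUE
MITF	CCATATGA	Vachtenheim & Borovansky 2010	TRUE
POU3F2	ATGCAAAT	Besch & Berking 2014, MITF promoter	TRUE
USF1	CATGTG	Bentley et al. 1994, tyrosinase M-box	TRUE
USF1	CACGTG	Loftus et al. 2009, E-box	TRUE
SOX10	AACAAA	Murisier et al. 2006	TRUE
SOX10	WWCAAW	Murisier et al. 2006, bracketed alternation as IUPAC	TRUE
SOX10	CATTGTC	Vance & Goding 2004, SOX10 site	TRUE
SOX10	WWCAAWG	Watanabe et al. 2002, bracketed alternation as IUPAC	TRUE
SOX10	CATTGAA	Watanabe et al. 2002, SOX10-s1	TRUE
SOX10	AACAAAA	Watanabe et al. 2002, SOX10-s4	TRUE
SOX10	TTTTGTT	Watanabe et al. 2002, SOX10-s3	TRUE
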