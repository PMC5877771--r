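entity1	entity2	provenance
CEBPB	CEBPD	Arijs-Rutgeerts-2009;Bahr-Bowler-2013;Mallon-McKay-2013;Roth-Zlotnik-2006;Salaverria-Siebert-2011;Wang-Maris-2006;Wu-Garvey-2007
EFNA1	EFNA4	Bild-Nevins-2006B;Innocenti-Brown-2011
EFNA3	EFNA4	Innocenti-Brown-2011;Salaverria-Siebert-2011
EFNA1	EFNA3	Gysin-McMahon-2012;Innocenti-Brown-2011
ALOX12	EPHA3	Ramaswamy-Golub-2001;Wang-Maris-2006
LYN	RRBP1	Alizadeh-Staudt-2000;Rieger-Chu-2004
CEBPB	TRIB1	Bahr-Bowler-2013;Rieger-Chu-2004
CLUL1	CLU	Mallon-McKay-2013
EFNA1	CEBPD	Gysin-McMahon-2012
MYBL2	CLUL1	Cheok-Evans-2003
TNC	CLU	Ramaswamy-Golub-2001
EFNA3	EFNA5	Roth-Zlotnik-2006
CEBPD	TRIB1	Bahr-Bowler-2013
TNC	KLF5	Perou-Botstein-1999
ALOX12	CLU	Burington-Shaughnessy-2008;Gysin-McMahon-2012
EFNA1	CLUL1	Rieger-Chu-2004
EFNA1	KLF5	Ramaswamy-Golub-2001;Salaverria-Siebert-2011
RRBP1	EFNA3	Arijs-Rutgeerts-2009
LYN	EFNA5	Perou-Botstein-1999
EFNA1	FBXW7	Kang-Willman-2010
NUCB2	KLF5	Wang-Maris-2006
EFNA1	CEBPB	Roth-Zlotnik-2006
LYN	CLU	Perou-Botstein-1999
NUCB2	RRBP1	Rieger-Chu-2004
FBXW7	EFNA5	Roth-Zlotnik-2006
LYN	CEBPB	Ramaswamy-Golub-2001
TNC	CEBPB	Arijs-Rutgeerts-2009
EFNA1	TNC	Ramaswamy-Golub-2001
EFNA4	CLUL1	Gysin-McMahon-2012
XRCC6	RRBP1	Bahr-Bowler-2013
EFNA3	TRIB1	Wang-Maris-2006
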