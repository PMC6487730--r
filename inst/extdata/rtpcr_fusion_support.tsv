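gene5	gene3	chrom5	chrom3	chromosomal	normal_samples	tumor_samples
C15orf57	CBX3	chr15	chr7	inter	N57/N93/N95/N100/N101/N127/N129/N130/N187/P2N/AN/BN	C57/C93/C100/C101/C120/C127/C129/C186/C187/AC/AV/BC1/BC2
IGLV1-51	IGLL5	chr22	chr22	intra	N93/N95/N101/N120/N129/N130/N187/P2N/AN/BN	C57/C93/C127/C120/C129/C130/C186/C187/P2L/P2R/AV/BC1/BC2
IGLV4-69	IGLJ3	chr22	chr22	intra	N95/N100/P2N	AC/AV
RP11-100N3.2	GNAS	chr11	chr20	inter	N57/N93/N95/N100/N101/N127/N129/N186/P2N	C93/C95/C127/C129/C130/C187/P2R/BC1
RP11-476K15.1	CTD-2015H3.2	chr18	chr18	intra	N129/N130/P2N/BN	C57/C93/C127/C129/C130/C186/C187/AV/BC1/BC2
XXbac-BPG248L24.12	EVA1B	chr6	chr1	inter	N57/N93/N95/N100/N101/N120/N127/N129/N130/N186/P2N/AN	C57/C93/C95/C101/C120/C127/C129/C130/C186/C187/P2L/P2R/AC/AV/BC1/BC2
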