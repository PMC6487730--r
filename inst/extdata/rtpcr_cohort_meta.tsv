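sample_id	patient_id	tissue	cohort
N57	PT57	normal	validation
C57	PT57	tumor	validation
N93	PT93	normal	validation
C93	PT93	tumor	validation
N95	PT95	normal	validation
C95	PT95	tumor	validation
N100	PT100	normal	validation
C100	PT100	tumor	validation
N101	PT101	normal	validation
C101	PT101	tumor	validation
N120	PT120	normal	validation
C120	PT120	tumor	validation
N127	PT127	normal	validation
C127	PT127	tumor	validation
N129	PT129	normal	validation
C129	PT129	tumor	validation
N130	PT130	normal	validation
C130	PT130	tumor	validation
N186	PT186	normal	validation
C186	PT186	tumor	validation
N187	PT187	normal	validation
C187	PT187	tumor	validation
P2N	PT_P2	normal	validation
P2L	PT_P2	tumor	validation
P2R	PT_P2	tumor	validation
AN	PT_A	normal	validation
AC	PT_A	tumor	validation
AV	PT_A	tumor	validation
BN	PT_B	normal	validation
BC1	PT_B	tumor	validation
BC2	PT_B	tumor	validation
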