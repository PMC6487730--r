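sample_id	raw_pairs	clean_pairs	unique_mapped
PI-N	43923285	39103125	37226847
PI-P	50352174	44682897	42769007
PI-M	52613930	46523611	44710681
PI-V	49053998	42656707	40867848
PII-N	45139012	39403503	37305981
PII-L	59886699	51922083	49206602
PII-R	56642919	51940040	48979659
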