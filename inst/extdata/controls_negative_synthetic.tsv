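name	spacer
NEG_SAFEHARBOR_SYNTH_01	CGGTGCGCCTTGTTCGTGCT
NEG_SAFEHARBOR_SYNTH_02	GTTCGGCTCGATGCCGCTCT
NEG_SAFEHARBOR_SYNTH_03	GTTAGCTAGAATAACTAGAG
NEG_SAFEHARBOR_SYNTH_04	CTTATCGTCCCTGTCGATCG
NEG_SAFEHARBOR_SYNTH_05	AATTCGTTTCCTACCATCTG
NEG_SAFEHARBOR_SYNTH_06	AATCTCTTAGATGTGCAAAT
NEG_SAFEHARBOR_SYNTH_07	GTTCACATAGACTCGTTATC
NEG_SAFEHARBOR_SYNTH_08	TTACGCAGCAGGGCGTCCTA
NEG_SAFEHARBOR_SYNTH_09	AATATGCGTGAGCTCTACTA
NEG_SAFEHARBOR_SYNTH_10	CATCGGTAGTCGTCAGCCTC
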