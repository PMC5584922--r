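name	spacer
POS_RIBOSOME_SYNTH_01	CACGATAGCCTGTTGACGTC
POS_RIBOSOME_SYNTH_02	AGGCAACCTTGTGCGTGGTC
POS_RIBOSOME_SYNTH_03	ATAGCTAGGCAATCTAACTC
POS_RIBOSOME_SYNTH_04	TTGTGAAGATATGTCAACCA
POS_RIBOSOME_SYNTH_05	TCTAAAGGGGAAAAGGCAAG
POS_RIBOSOME_SYNTH_06	AGGGGCGCGGGTCCCAGAGG
POS_RIBOSOME_SYNTH_07	CAGGCGCACTGATCTCTTGA
POS_RIBOSOME_SYNTH_08	TTGTGCCACTCGGTGCCTCT
POS_RIBOSOME_SYNTH_09	TGCTCTTCTGTAAAGTCACC
POS_RIBOSOME_SYNTH_10	CACCTCTTACTCCTTCGCAG
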