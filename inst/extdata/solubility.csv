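key,value,units,source,version
Y,0.045,g/100 g water,"aqueous solubility of tyrosine at 25 C, literature compilation",2024
F,2.79,g/100 g water,"aqueous solubility of phenylalanine at 25 C, literature compilation",2024
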