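key,value,units,source,version
F,-7.26,RT,"Miyazawa & Jernigan (1996) J Mol Biol 256:623-644, diagonal contact energy e_FF",1996
Y,-4.17,RT,"Miyazawa & Jernigan (1996) J Mol Biol 256:623-644, diagonal contact energy e_YY",1996
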