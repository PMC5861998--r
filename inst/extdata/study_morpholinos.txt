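t_splice	TGGAGAGACCCTGATCTTACCTTCC
t_transl	GGCTTCCAAGCGCACACACTGGG
t2_splice	GAAAGGTCCATATTCTCTTACCTTC
t2_transl	AGCTGTGCCTGTGCTCATTGTATTG
cMO	CCTCTTACCTCAGTTACAATTTATA
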