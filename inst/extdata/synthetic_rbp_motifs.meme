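MEME version 4

ALPHABET= ACGT

strands: +

Background letter frequencies
A 0.25 C 0.25 G 0.25 T 0.25

MOTIF SYN_GARICH synthetic GA-rich element
letter-probability matrix: alength= 4 w= 7 nsites= 20 E= 0
 0.850000  0.050000  0.050000  0.050000
 0.050000  0.050000  0.850000  0.050000
 0.850000  0.050000  0.050000  0.050000
 0.050000  0.050000  0.850000  0.050000
 0.850000  0.050000  0.050000  0.050000
 0.050000  0.050000  0.850000  0.050000
 0.850000  0.050000  0.050000  0.050000

MOTIF SYN_UCUCU synthetic pyrimidine tract
letter-probability matrix: alength= 4 w= 6 nsites= 20 E= 0
 0.040000  0.100000  0.040000  0.820000
 0.040000  0.820000  0.100000  0.040000
 0.040000  0.100000  0.040000  0.820000
 0.040000  0.820000  0.100000  0.040000
 0.040000  0.100000  0.040000  0.820000
 0.040000  0.820000  0.100000  0.040000

MOTIF SYN_GCAUG synthetic fox-like element
letter-probability matrix: alength= 4 w= 5 nsites= 20 E= 0
 0.030000  0.030000  0.910000  0.030000
 0.030000  0.910000  0.030000  0.030000
 0.910000  0.030000  0.030000  0.030000
 0.030000  0.030000  0.030000  0.910000
 0.030000  0.030000  0.910000  0.030000
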