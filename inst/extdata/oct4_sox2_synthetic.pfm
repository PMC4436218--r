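>SYN0001	Oct4-Sox2-composite (synthetic stand-in PFM, 15 bp)
A [  5 85  5  5  5  5 20 55  5  5  5 85 70 85  5 ]
C [ 85  5  5  5  5  5 10 10  5  5 85  5 10  5  5 ]
G [  5  5  5  5 85  5 10 10  5 85  5  5 10  5  5 ]
T [  5  5 85 85  5 85 60 25 85  5  5  5 10  5 85 ]
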