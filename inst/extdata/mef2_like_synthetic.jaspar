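>SYN0001.1 MEF2-like_synthetic
A [  2 10  1 60 55 58 52 61  2 55 ]
C [ 55  3  2  1  2  1  3  1  1  4 ]
G [  4  2  2  2  3  2  4  1  3 58 ]
T [  5 51 61  3  6  5  7  3 60  9 ]
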