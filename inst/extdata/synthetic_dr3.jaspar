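>SYNTH_DR3 synthetic RXR/VDR-style DR3 matrix (constructed stand-in, not a database matrix)
A [ 14  2  1  1  1 16  5  5  5 14  2  1  1  1 16 ]
C [  2  1  1  1 14  2  5  5  5  1  1  1  2 14  2 ]
G [  2 16 14  2  1  1  5  5  5  4 16 12  1  1  1 ]
T [  2  1  4 16  4  1  5  5  5  1  1  6 16  4  1 ]
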