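>BREd_synthetic synthetic TFIIB recognition element, downstream (RTDKKKK)
A  [ 40  8 30  8  8  8  8 ]
C  [  8  8  8  8  8  8  8 ]
G  [ 40  8 30 42 42 42 42 ]
T  [ 12 76 32 42 42 42 42 ]
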