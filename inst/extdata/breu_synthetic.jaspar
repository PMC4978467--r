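>BREu_synthetic synthetic TFIIB recognition element, upstream (SSRCGCC)
A  [ 10 10 40  5  5  5  5 ]
C  [ 40 40  5 75  5 75 75 ]
G  [ 40 40 45 10 80 10 10 ]
T  [ 10 10 10 10 10 10 10 ]
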