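>TATA_synthetic synthetic sharp TATA-box region matrix (GC / TATAWAWA core / G-rich downstream)
A  [   3   3   3 990   3 990 495 990 495 990   3   3   3   3 ]
C  [   3 990   3   3   3   3   3   3   3   3   3   3 990   3 ]
G  [ 990   3   3   3   3   3   3   3   3   3 990 990   3 990 ]
T  [   3   3 990   3 990   3 495   3 495   3   3   3   3   3 ]
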