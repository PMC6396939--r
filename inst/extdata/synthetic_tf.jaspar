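>SYN0001.1 synthTF (synthetic test motif, consensus TGACGTCA)
A  [  1  1 97  1  1  1  1 97 ]
C  [  1  1  1 97  1  1 97  1 ]
G  [  1 97  1  1 97  1  1  1 ]
T  [ 97  1  1  1  1 97  1  1 ]
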