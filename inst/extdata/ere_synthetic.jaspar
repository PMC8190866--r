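>ERE_SYN synthetic estrogen response element count matrix (core consensus AGGTCAnnnTGACCT; transition-tolerant half sites, anchor positions 4, 5 and 12)
A  [ 45 45 45  5  5 45 25 25 25  5 45 45  5  5  5 ]
C  [  5  5  5  5 45  5 25 25 25 45  5  5 45 45 45 ]
G  [ 45 45 45  5  5 45 25 25 25  5 45  5  5  5  5 ]
T  [  5  5  5 45  5  5 25 25 25 45  5  5 45 45 45 ]
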