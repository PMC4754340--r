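>synthetic_gpref synthetic demonstration motif (G-preferring core; not derived from any database)
A [ 6 1 0 1 6 ]
C [ 2 1 0 1 2 ]
G [ 2 16 20 16 2 ]
T [ 10 2 0 2 10 ]
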