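6.5
6.5
6.5
2
8
8
8
2
10
10
10
3
7
7
7
3
6
6
6
2
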