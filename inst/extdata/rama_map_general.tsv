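2 2 3 3 4 4 4 4 3 3 3 3 3 3 3 3 3 3 3 3 4 4 4 4 3 3 2 2 2 2 2 2 2 2 2 2
1 2 3 3 4 4 4 4 3 3 2 2 2 2 2 2 2 2 3 3 4 4 4 4 3 3 2 1 1 1 1 1 1 1 1 1
1 2 3 3 4 4 4 4 3 3 2 1 1 1 1 1 1 2 3 3 4 4 4 4 3 3 2 1 1 1 1 1 1 1 1 1
1 2 3 3 4 4 4 4 3 3 2 1 1 1 1 1 1 2 3 3 4 4 4 4 3 3 2 1 1 1 1 1 1 1 1 1
1 2 3 3 4 4 4 4 3 3 2 1 1 1 1 1 1 2 3 3 4 4 4 4 3 3 2 1 1 1 1 1 1 1 1 1
1 2 3 3 4 4 4 4 3 3 2 1 1 1 1 1 1 2 3 3 4 4 4 4 3 3 2 1 1 1 1 1 1 1 1 1
1 2 3 3 4 4 4 4 3 3 2 1 1 1 1 1 1 2 3 3 4 4 4 4 3 3 2 1 1 1 1 1 1 1 1 1
1 2 3 3 4 4 4 4 3 3 2 1 1 1 1 1 1 2 3 3 4 4 4 4 3 3 2 1 1 1 1 1 1 1 1 1
1 2 3 3 4 4 4 4 3 3 2 1 1 1 1 1 1 2 3 3 4 4 4 4 3 3 2 1 1 1 1 1 1 1 1 1
1 2 3 3 4 4 4 4 3 3 2 1 1 1 1 1 1 2 3 3 4 4 4 4 3 3 2 1 1 1 1 1 1 1 1 1
1 2 3 3 4 4 4 4 3 3 2 1 1 1 1 1 1 2 3 3 4 4 4 4 3 3 2 1 1 1 1 1 1 1 1 1
1 2 3 3 4 4 4 4 3 3 2 1 1 1 1 1 1 2 3 3 4 4 4 4 3 3 2 1 1 1 1 1 1 1 1 1
1 2 3 3 4 4 4 4 3 3 2 1 1 1 1 1 1 2 3 3 4 4 4 4 3 3 2 1 1 1 1 1 1 1 1 1
2 2 3 3 4 4 4 4 3 3 2 1 1 1 1 1 1 2 3 3 4 4 4 4 3 3 2 2 2 2 2 2 2 2 2 2
3 3 3 3 4 4 4 4 3 3 2 2 2 2 2 2 2 2 3 3 4 4 4 4 3 3 3 3 3 3 3 3 3 3 3 3
3 3 3 3 4 4 4 4 3 3 3 3 3 3 3 3 3 3 3 3 4 4 4 4 3 3 3 3 3 3 3 3 3 3 3 3
4 4 4 4 4 4 4 4 3 3 3 3 3 3 3 3 3 3 3 3 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4
4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4
4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4
4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 3 3 3 3 3 3 3 3 3 3 3 3 4 4 4 4 4 4 4 4 4
4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 3 3 3 3 3 3 3 3 3 3 3 3 4 4 4 4 4 4 4 4 4
4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 3 3 2 2 2 2 2 2 2 2 3 3 4 4 4 4 4 4 4 4 4
4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 3 3 2 1 1 1 1 1 1 2 3 3 4 4 4 4 4 4 4 4 4
4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 3 3 2 1 1 1 1 1 1 2 3 3 4 4 4 4 4 4 4 4 4
4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 3 3 2 1 1 1 1 1 1 2 3 3 4 4 4 4 4 4 4 4 4
4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 3 3 2 1 1 1 1 1 1 2 3 3 4 4 4 4 4 4 4 4 4
4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 3 3 2 2 2 2 2 2 2 2 3 3 4 4 4 4 4 4 4 4 4
4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 3 3 3 3 3 3 3 3 3 3 3 3 4 4 4 4 4 4 4 4 4
4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 3 3 3 3 3 3 3 3 3 3 3 3 4 4 4 4 4 4 4 4 4
4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4
4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4
4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4
4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4
4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4
3 3 3 3 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 4 3 3 3 3 3 3 3 3 3 3 3 3
3 3 3 3 4 4 4 4 3 3 3 3 3 3 3 3 3 3 3 3 4 4 4 4 3 3 3 3 3 3 3 3 3 3 3 3
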