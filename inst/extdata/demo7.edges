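# seven-node demonstration network: triangle {1,2,3} bridged to {4,5,6,7}
1 2
1 3
2 3
3 4
4 5
4 6
4 7
5 6
5 7
6 7
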