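value,group
1956,Group 1
3828,Group 1
2051,Group 1
3721,Group 1
3233,Group 1
2000,Group 1
4000,Group 1
4428,Group 1
2603,Group 1
2370,Group 1
820,Group 2
3364,Group 2
1957,Group 2
1851,Group 2
2984,Group 2
744,Group 2
2044,Group 2
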