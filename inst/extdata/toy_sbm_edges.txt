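0 1
0 2
1 2
0 3
1 3
1 4
2 4
3 4
0 5
3 5
4 5
0 6
1 6
2 6
3 6
4 6
5 6
0 7
2 7
3 7
4 7
5 7
4 8
6 9
0 11
2 11
6 11
0 14
7 14
8 9
8 10
9 10
9 11
9 12
9 13
12 13
8 14
9 14
10 14
11 14
12 14
8 15
10 15
12 15
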