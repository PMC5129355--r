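37
1 2 2 7
2 3 1 3 8
3 3 2 4 9
4 3 3 5 10
5 3 4 6 11
6 2 5 12
7 3 1 8 13
8 4 2 7 9 14
9 4 3 8 10 15
10 4 4 9 11 16
11 4 5 10 12 17
12 3 6 11 18
13 3 7 14 19
14 4 8 13 15 20
15 4 9 14 16 21
16 4 10 15 17 22
17 4 11 16 18 23
18 3 12 17 24
19 3 13 20 25
20 4 14 19 21 26
21 4 15 20 22 27
22 4 16 21 23 28
23 4 17 22 24 29
24 3 18 23 30
25 3 19 26 31
26 4 20 25 27 32
27 4 21 26 28 33
28 4 22 27 29 34
29 4 23 28 30 35
30 3 24 29 36
31 2 25 32
32 3 26 31 33
33 3 27 32 34
34 3 28 33 35
35 3 29 34 36
36 3 30 35 37
37 1 36
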