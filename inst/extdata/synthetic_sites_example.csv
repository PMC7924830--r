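site_id,x_km,y_km,clade
1,62.5,127.5,G
2,272.5,52.5,C
3,237.5,97.5,G
4,262.5,47.5,C
5,92.5,147.5,G
6,112.5,17.5,G
7,212.5,62.5,G
8,2.5,137.5,F
9,272.5,57.5,C
10,252.5,92.5,C
11,157.5,47.5,G
12,67.5,132.5,G
13,162.5,57.5,G
14,162.5,47.5,G
15,297.5,122.5,F
16,107.5,17.5,G
17,32.5,57.5,G
18,17.5,77.5,G
19,237.5,12.5,G
20,2.5,52.5,G
21,197.5,17.5,G
22,52.5,12.5,G
23,252.5,147.5,F
24,162.5,127.5,G
25,297.5,57.5,C
26,57.5,132.5,G
27,202.5,57.5,G
28,232.5,92.5,G
29,152.5,127.5,G
30,242.5,22.5,C
31,132.5,97.5,G
32,187.5,137.5,G
33,292.5,37.5,C
34,117.5,57.5,G
35,47.5,102.5,G
36,182.5,127.5,G
37,202.5,52.5,G
38,197.5,2.5,G
39,232.5,62.5,G
40,237.5,142.5,F
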