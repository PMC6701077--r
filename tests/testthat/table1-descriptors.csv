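group_id,d1,d2,d3,d4,d5,d6,d7,d8
1,0,0,1,1,0,0,0,0
2,0,0,1,0,0,0,0,0
3,0,0,1,0,0,0,0,0
4,0,0,1,0,0,0,0,0
5,0,0,2,1,0,0,0,1
6,0,0,2,0,0,0,0,1
7,0,0,2,0,0,0,0,1
8,0,0,2,0,0,0,0,1
9,0,0,1,0,0,1,0,0
10,0,0,1,0,0,1,0,0
11,0,0,2,0,0,1,0,0
12,0,0,2,0,0,1,0,0
13,0,0,2,0,0,1,0,0
14,0,0,1,1,1,0,0,0
15,1,0,2,0,1,0,0,0
16,1,0,1,0,1,0,0,0
17,0,0,2,0,1,1,0,0
18,0,0,3,1,1,0,0,1
19,0,0,3,0,1,0,0,1
20,0,0,2,1,1,0,0,1
21,0,0,4,1,2,0,0,1
22,0,0,4,0,2,0,0,1
23,0,0,3,1,2,0,0,1
24,0,0,2,1,1,0,0,0
25,0,0,2,0,1,0,0,0
26,0,0,2,0,1,0,0,0
27,0,0,2,0,1,1,0,0
28,1,0,2,0,1,0,0,0
29,0,0,2,1,1,0,0,0
30,0,0,2,0,1,0,0,0
31,0,0,2,1,1,0,0,0
32,0,0,2,0,1,0,0,0
33,0,0,2,0,1,0,0,0
34,0,0,2,0,1,0,0,0
35,0,0,2,0,1,0,0,0
36,0,0,2,0,1,1,0,0
37,1,0,6,0,1,1,0,0
38,0,0,6,1,1,1,0,0
39,0,0,6,0,1,1,0,0
40,1,0,3,0,1,0,1,0
41,0,0,3,1,1,0,1,0
42,0,0,3,1,2,0,0,1
43,1,0,3,0,2,0,0,1
44,0,1,2,1,1,0,0,0
45,0,1,2,0,1,0,0,0
46,0,1,2,0,1,0,0,0
47,1,0,3,0,2,0,0,0
48,0,1,3,1,2,0,0,0
49,0,1,3,0,2,0,0,0
50,1,0,4,0,3,0,0,0
51,0,1,4,1,3,0,0,0
52,1,0,5,0,4,0,0,0
53,0,1,2,0,1,1,0,0
54,0,0,4,1,3,0,0,1
55,0,0,4,0,3,0,0,1
56,0,0,4,0,3,0,0,1
57,0,0,4,0,3,1,0,1
58,1,0,3,0,2,0,0,2
59,1,0,2,0,1,0,0,0
60,0,0,2,1,1,0,0,0
61,1,0,7,0,2,1,0,1
62,1,0,4,0,2,0,0,0
63,0,1,1,1,1,0,0,0
64,0,1,1,1,1,0,0,0
65,0,0,2,1,0,0,1,0
66,0,0,2,0,0,0,1,0
67,1,0,4,0,2,0,0,1
68,1,0,4,0,1,0,1,1
69,0,1,3,1,1,0,0,0
70,0,0,2,0,0,0,0,1
71,0,1,2,0,1,1,0,0
72,1,0,5,0,2,0,0,1
73,0,0,5,0,2,0,0,1
74,0,1,4,1,3,0,0,0
75,0,1,3,0,2,0,0,0
76,0,1,2,0,1,0,0,0
77,0,0,3,0,2,0,0,1
78,0,0,1,1,1,0,0,0
79,0,0,1,0,1,0,0,0
80,0,0,1,0,1,0,0,0
81,0,0,1,0,1,0,0,0
82,0,0,2,0,2,0,0,0
83,0,0,2,0,2,0,0,0
84,0,0,2,0,2,0,0,0
85,1,0,7,0,2,0,0,1
86,1,0,5,0,4,0,0,0
87,0,1,4,1,3,0,0,0
88,1,0,4,0,3,0,0,0
89,0,1,3,1,2,0,0,0
90,0,1,4,1,3,0,0,0
91,1,0,4,0,3,0,0,0
92,1,0,5,0,4,0,0,0
93,1,0,5,0,4,0,0,0
94,0,0,3,1,2,0,0,1
95,0,0,4,1,2,0,0,1
96,0,0,4,0,2,0,0,1
97,0,0,5,1,2,0,0,1
98,0,0,5,0,2,0,0,1
99,0,0,5,0,2,0,0,1
100,0,0,4,1,2,0,0,0
101,0,0,4,0,2,0,0,0
102,0,0,2,1,1,0,0,0
103,0,0,2,0,1,0,0,0
104,0,0,2,0,1,0,0,0
105,1,0,6,0,2,0,0,0
106,1,0,5,0,1,1,0,0
107,0,0,5,1,1,1,0,0
108,0,0,5,0,1,1,0,0
109,0,0,3,1,2,0,0,2
118,0,0,5,0,3,0,0,2
119,0,0,5,0,3,0,0,2
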