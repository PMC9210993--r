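# Color lookup table: id name R G B A  # modality=<tag>
1    V1-             52 118 148 255  # modality=visual
2    V1+             55 170 230 255  # modality=visual
3    V2-             46 150 210 255  # modality=visual
4    V2+             18 104 159 255  # modality=visual
5    V3              20 109 173 255  # modality=visual
6    VP              46 105 151 255  # modality=visual
7    DI              11 108 193 255  # modality=visual
8    V3A             83 135 186 255  # modality=visual
9    V3B              9  91 180 255  # modality=visual
10   OPA             19  95 187 255  # modality=visual
11   LO1             36  82 144 255  # modality=visual
12   LO2             65 118 197 255  # modality=visual
13   LO3             71 106 165 255  # modality=visual
14   PGp             72 124 225 255  # modality=visual
15   V6              37  72 146 255  # modality=visual
16   V6A             37  76 171 255  # modality=visual
17   aPOS            13  52 158 255  # modality=visual
18   POm             41  65 141 255  # modality=visual
19   ProS1           20  63 223 255  # modality=visual
20   ProS2           61  85 192 255  # modality=visual
21   MT-             23  52 201 255  # modality=visual
22   MT+             20  42 187 255  # modality=visual
23   MTc             34  53 202 255  # modality=visual
24   MSTd            86  98 232 255  # modality=visual
25   MSTv            49  55 149 255  # modality=visual
26   FSTd            70  73 171 255  # modality=visual
27   STV1            40  41 211 255  # modality=visual
28   STV2            36  32 185 255  # modality=visual
29   7b-PICv         40  33 172 255  # modality=visual
30   7b-PICv,s       86  78 182 255  # modality=visual
31   V4v             42  23 204 255  # modality=visual
32   hV4             34  18 143 255  # modality=visual
33   V8              87  71 174 255  # modality=visual
34   PITd            75  47 198 255  # modality=visual
35   PH              71  48 157 255  # modality=visual
36   FFC             97  63 207 255  # modality=visual
37   VVC             56  17 168 255  # modality=visual
38   VO1            106  62 216 255  # modality=visual
39   VO2            127  83 224 255  # modality=visual
40   V7              91  26 218 255  # modality=visual
41   cIPS            88  31 186 255  # modality=visual
42   LIP0            98  41 186 255  # modality=visual
43   LIP1            89  19 187 255  # modality=visual
44   PEc             78  22 149 255  # modality=visual
45   IPS4            97  36 166 255  # modality=visual
46   IPS5           119  17 222 255  # modality=visual
47   aPCu1          112  43 174 255  # modality=visual
48   aPCu2          106  52 151 255  # modality=visual
49   VIP1v          103  37 151 255  # modality=visual
50   VIP1v,s        146  81 188 255  # modality=visual
51   VIP2v          138  72 178 255  # modality=visual
52   VIP2v,s        177  57 240 255  # modality=visual
53   dmFEF          121  34 161 255  # modality=visual
54   FEF            190  64 242 255  # modality=visual
55   6a             152  42 191 255  # modality=visual
56   DLPFC          134  40 164 255  # modality=visual
57   DLPFCa         135  48 159 255  # modality=visual
58   A1             150  53  52 255  # modality=auditory
59   R              210  43  39 255  # modality=auditory
60   RT             192  66  61 255  # modality=auditory
61   MM             157  58  52 255  # modality=auditory
62   RM             160  55  48 255  # modality=auditory
63   CM             159  45  35 255  # modality=auditory
64   CL             237 116 104 255  # modality=auditory
65   ML             197  51  34 255  # modality=auditory
66   AL             201  56  36 255  # modality=auditory
67   RTL            192  47  24 255  # modality=auditory
68   CP             164  38  16 255  # modality=auditory
69   MPc            141  37  17 255  # modality=auditory
70   MPr            154  40  15 255  # modality=auditory
71   RP             156  68  47 255  # modality=auditory
72   TA2            221  86  52 255  # modality=auditory
73   TA3            190 101  76 255  # modality=auditory
74   CA4            230  92  50 255  # modality=auditory
75   MA4            141  66  41 255  # modality=auditory
76   RA4            225 115  76 255  # modality=auditory
77   CA5            215 104  62 255  # modality=auditory
78   MA5            235 126  82 255  # modality=auditory
79   RA5            209  97  48 255  # modality=auditory
80   43aud          227 124  76 255  # modality=auditory
81   PSaud1         240 144  96 255  # modality=auditory
82   PSaud2         220 133  86 255  # modality=auditory
83   3aud           216 105  43 255  # modality=auditory
84   dmFAF          149  70  23 255  # modality=auditory
85   p32aud         224 130  70 255  # modality=auditory
86   PZa,v,s        204 134  87 255  # modality=auditory
87   PZa,s          226 114  34 255  # modality=auditory
88   DLPFCaud       185  95  28 255  # modality=auditory
89   IFSp           230 131  52 255  # modality=auditory
90   45aud          214 133  65 255  # modality=auditory
91   FOPaud         154  91  34 255  # modality=auditory
92   3b-fa          209 200  73 255  # modality=somatosensory
93   3b-ha          162 164  22 255  # modality=somatosensory
94   3b-ft          218 230  95 255  # modality=somatosensory
95   3a-fa          126 146  22 255  # modality=somatosensory
96   3a-ha          189 242  21 255  # modality=somatosensory
97   3a-ft          114 156  21 255  # modality=somatosensory
98   1-fa           175 225  95 255  # modality=somatosensory
99   1-ha           164 242  73 255  # modality=somatosensory
100  1-ft           119 189  58 255  # modality=somatosensory
101  2               90 186  28 255  # modality=somatosensory
102  5m             114 208  72 255  # modality=somatosensory
103  pCI             83 174  55 255  # modality=somatosensory
104  5L              62 205  34 255  # modality=somatosensory
105  PFt             72 204  59 255  # modality=somatosensory
106  AIPv,s          50 225  48 255  # modality=somatosensory
107  S-II            27 142  34 255  # modality=somatosensory
108  PV              54 155  68 255  # modality=somatosensory
109  Ig              67 234 103 255  # modality=somatosensory
110  FOP2            29 159  66 255  # modality=somatosensory
111  PHt             52 197 104 255  # modality=somatosensory
112  4-fa           150 153  53 255  # modality=motor
113  4-ha           109 146  12 255  # modality=motor
114  4-fo            77 144  16 255  # modality=motor
115  6d             106 209  77 255  # modality=motor
116  SMA1            57 206  60 255  # modality=motor
117  SMA2           101 227 136 255  # modality=motor
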