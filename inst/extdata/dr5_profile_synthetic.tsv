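# Synthetic stand-in for a digitized DR5::GUS staining-density line scan
# along the central root axis (cell positions from the root end). Generated
# from the basic-set stationary auxin profile by an affine intensity
# transform plus Gaussian densitometry noise (sd 2.5, seed 20100721). It is
# NOT experimental data; it exercises the profile-comparison machinery.
position	intensity
1	129.38
2	135.98
3	130.05
4	144.07
5	165.97
6	55.14
7	35.55
8	29.29
9	29.95
10	28.19
11	25.65
12	29.21
13	25.99
14	28.38
15	32.84
16	29.64
17	31.13
18	26.5
19	27.84
20	29.22
21	24.09
22	29.97
23	30.93
24	31.29
25	31.52
26	30.3
27	29.82
28	29.43
29	32.77
30	31.28
31	30.34
32	27.45
33	32.74
34	29.47
35	33.89
36	34.68
37	31.2
38	33.23
39	29.23
40	31.52
41	34.93
42	31.98
43	24.76
44	35.03
45	34.35
46	34.05
47	30.67
48	38.84
49	27.53
50	33.09
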