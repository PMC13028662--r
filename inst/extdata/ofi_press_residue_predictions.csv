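run_id,FCRC,AlCl3
1,136.4,33.77
2,128.23,31.92
3,327.34,31.16
4,133.38,40.95
5,337.34,32.52
6,313.28,37.44
7,365.65,44.47
8,362.78,37.24
9,313.08,34.23
10,343.01,34.39
11,354.95,38.51
12,152.29,23.07
13,131.92,31.01
14,347.4,37.41
15,366.6,51.15
16,373.37,46.23
17,365.28,42.38
18,375.2,46.09
19,355.12,35.24
20,362.78,37.24
21,355.39,36.38
22,322.46,31.93
23,362.78,37.24
24,329.17,41.05
25,326.78,36.77
26,324.84,39.47
27,135.88,28.72
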