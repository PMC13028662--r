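run_id,pattern,ethanol,power,time,ratio,FCRC_mean,FCRC_sd,AlCl3_mean,AlCl3_sd
1,+0+0,100,600,4,40,136.87,0.47,32.21,0.99
2,+00-,100,600,3,30,125.02,1.42,29.73,3.18
3,00-+,75,600,2,50,323.18,3.32,31.44,0.23
4,+-00,100,400,3,40,128.18,3.59,42.9,1.38
5,0+-0,75,800,2,40,330.76,3.59,31.21,1.18
6,00--,75,600,2,30,308.91,2.17,38.82,0.6
7,00++,75,600,4,50,370,2.74,44.43,5.8
8,0000,75,600,3,40,365.56,1.91,37.64,0.45
9,0-0-,75,400,3,30,316.65,1.42,34.75,0.23
10,0+0-,75,800,3,30,343.35,3.01,35.24,1.38
11,0-0+,75,400,3,50,360.99,0.72,37.41,2.19
12,++00,100,800,3,40,159.78,1.19,24.42,0.6
13,+0-0,100,600,2,40,138.24,3.98,30.95,1.64
14,0-+0,75,400,4,40,347.62,0.72,37.64,0.6
15,-+00,50,800,3,40,371.79,0.99,50.53,1.77
16,-00+,50,600,3,50,370.21,2.43,47.34,3.16
17,0++0,75,800,4,40,356.04,1.66,42.88,1.18
18,-0+0,50,600,4,40,375.26,1.71,45.92,5.41
19,--00,50,400,3,40,347.62,3.68,35.23,2.19
20,0000,75,600,3,40,362.73,0.27,37.73,1.59
21,0+0+,75,800,3,50,358.21,4.67,35.61,2.75
22,00+-,75,600,4,30,329.61,3.28,32.98,0.68
23,0000,75,600,3,40,360.05,3.32,36.34,3.87
24,-0-0,50,600,2,40,335.09,2.24,42.36,1.2
25,-00-,50,600,3,30,326.29,1.19,35.16,0.39
26,0--0,75,400,2,40,327.71,2.61,37.88,1.27
27,+00+,100,600,3,50,130,4.57,29.24,0.68
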