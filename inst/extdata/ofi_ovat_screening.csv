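parameter,level,FCRC_mean,FCRC_sd,AlCl3_mean,AlCl3_sd
solvent,water,161.62,0.88,23.18,0.51
solvent,ethanol,296.59,2.32,30.37,0.96
solvent,acetone,214.45,1.31,20.21,0.55
solvent,methanol,220.51,3.48,21.77,0.6
ethanol_pct,30,257.92,1.91,24.6,0.81
ethanol_pct,50,300.9,0.76,36.35,0.42
ethanol_pct,70,303.42,1.16,22.29,0.64
ethanol_pct,100,138.52,2.09,20.62,0.67
power_W,200,228.35,1.16,24.91,0.87
power_W,400,265.76,2.87,27.07,0.16
power_W,500,303.42,2.44,32.57,0.63
power_W,700,280.16,1.58,23.18,0.51
power_W,800,220.77,1.58,26.07,0.48
time_min,1,243.26,2.01,27.91,0.4
time_min,1.5,265.5,2.44,27.54,0.72
time_min,2,303.67,2.32,24.97,0.51
time_min,3,344.11,1.52,37.08,0.79
time_min,4,242.5,1.31,16.94,0.55
time_min,5,240.99,0.76,15,0.48
ratio_mL_g,10,193.97,0.76,33.57,0.79
ratio_mL_g,20,344.11,1.52,43.22,0.66
ratio_mL_g,30,358.27,1.16,54.97,0.48
ratio_mL_g,40,379,1.31,59.38,0.8
ratio_mL_g,50,267.53,3.48,41.54,0.32
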