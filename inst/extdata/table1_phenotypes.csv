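station,sample,date,VTG,E2,Cort,T4,T,IGF_I,calc_age,SL
LA,27,6/13/2006,0.05,417.6,2.72,28.95,1.47,29.39,8,16
LA,41,6/20/2006,0.06,590.3,54.4,31.93,1.72,21.76,8,16
LA,46,6/20/2006,0.12,261.3,95.6,37.59,0.96,28.7,9,17.1
PV,15,6/7/2006,0.09,716.8,14.33,27.55,1.22,32.52,8,16.5
PV,25,6/7/2006,0.06,569.2,5.25,14.23,0.73,36.93,8,16.7
OC,7,5/23/2006,0.07,116.2,87.02,27.09,1.35,20.34,7,15
OC,13,5/23/2006,0.03,156.1,30.22,32.34,1.97,22.39,7,15.5
OC,20,5/23/2006,0.04,200.5,79.2,33.61,1.58,23.61,6,14
OC,29,5/25/2006,0.04,151.6,46.99,3.89,1.21,25.58,7,15
OC,34,5/25/2006,0.09,281.3,40.37,34.29,1.69,20.67,6,13
OC,37,5/25/2006,0.37,219.2,41.91,37.04,1.43,23.89,7,15.4
OC,43,5/25/2006,0.15,274.8,26.5,28.09,1.6,17.87,7,14.8
DP,3,5/23/2006,0.05,1512.6,143.64,53.94,1.3,8.46,7,15.3
DP,8,5/23/2006,0.07,1102,49.43,28.79,2.12,15.24,7,14.9
DP,29,5/23/2006,0.01,321.1,23.42,41.32,0.74,25.74,8,16
DP,32,5/23/2006,0.03,1209.3,26.32,36.95,1.13,22.91,6,13.7
DP,37,6/30/2006,0.06,493.7,31.64,105.4,3.56,34.01,7,14.4
DP,39,6/30/2006,0.03,268.1,39.47,55,3.58,25.43,6,13.2
DP,44,6/30/2006,0.01,611.7,1.12,46.59,2.37,27.32,8,16
SD,7,6/22/2006,0.08,1988.4,56.77,16.46,1.74,24.89,6,12.3
SD,29,6/22/2006,0.2,377.9,7.71,47.49,1.99,25.93,6,12.2
SD,46,6/23/2006,0.06,473.7,86.95,47.37,0.84,32.71,6,11.4
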