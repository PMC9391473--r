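parameter,tissue,statistic,mean_all,sd_all,inter_var,intra_var,cv_percent,icc
PD,GM,mean,0.87,0.04,1.2e-3,7.6e-4,2.6,0.62
PD,GM,sd,0.18,0.02,2.8e-4,1.0e-4,4.4,0.73
PD,WM,mean,0.66,0.03,6.6e-4,2.9e-4,2.3,0.69
PD,WM,sd,0.12,0.01,1.4e-4,4.9e-5,4.7,0.74
PD,CSF,mean,1,,,,,
PD,CSF,sd,0.36,0.04,1.1e-3,4.3e-4,4.5,0.71
T1,GM,mean,1450,40,1344,79,0.5,0.94
T1,GM,sd,212,9,66,17,1.5,0.80
T1,WM,mean,940,20,505,6,0.2,0.99
T1,WM,sd,72,6,36,3,1.9,0.93
T1,CSF,mean,2570,170,23650,6860,2.6,0.78
T1,CSF,sd,920,217,41280,5899,5.2,0.87
T2,GM,mean,40,2,2.80,0.07,0.4,0.98
T2,GM,sd,7.0,0.5,0.21,0.01,1.5,0.94
T2,WM,mean,32,1,1.1,0.1,0.6,0.92
T2,WM,sd,4.2,0.2,0.038,0.008,1.9,0.82
T2,CSF,mean,102,19,366,13,3.2,0.97
T2,CSF,sd,84,16,231,11,3.4,0.96
Na,GM,mean,0.35,0.02,2.8e-4,6.0e-5,1.8,0.82
Na,GM,sd,0.08,0.02,1.8e-4,1.2e-4,6.9,0.61
Na,WM,mean,0.31,0.02,2.9e-4,8.2e-5,2.5,0.78
Na,WM,sd,0.06,0.01,9.1e-5,1.8e-5,4.6,0.84
Na,CSF,mean,0.50,0.04,1.4e-3,4.3e-4,3.3,0.76
Na,CSF,sd,0.15,0.03,9.0e-4,1.2e-4,5.2,0.88
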