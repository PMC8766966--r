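drug,n_saliva,saliva_median,n_plasma,plasma_median,n_urine,urine_median,sp_ratio_median
ATE,1,38.60,1,100.72,1,4839.48,0.38
NBV,6,0.74,3,0.57,3,0.63,9.50
AML,21,6.13,14,6.29,12,177.93,0.67
NFD,2,1.77,2,36.22,2,NA,0.05
DOX,6,3.01,4,7.12,4,55.11,0.32
OLM,7,0.22,3,244.94,2,1039.36,0.0009
TEL,13,2.60,9,45.82,9,11.57,0.02
VAL,2,2.19,2,749.78,2,2094.50,0.0029
RAM,6,0.13,5,0.73,5,9.30,0.10
RAM-M,6,0.11,5,11.12,5,384.26,0.01
HCTZ,6,6.23,2,10.82,2,538.22,10.48
CHL,4,5.35,3,50.50,3,906.77,0.17
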