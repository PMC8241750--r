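Patient,TBR_stat,TBR_dual,TBR_ratio,CBR_stat,CBR_dual,CBR_ratio,FWHM_stat,FWHM_dual,FWHM_ratio
1,1.34,1.51,13,2.59,4.24,64,12.2,11.63,-5
2,1.45,1.51,4,4.43,4.80,8,12.54,9.9,-21
3,1.30,1.21,-7,3.22,2.30,-29,7.6,7.84,3
4,3.10,3.41,10,15.15,18.76,24,23.71,17.91,-24
5,1.11,1.24,12,1.02,2.12,107,18.72,12.39,-34
5,1.58,1.68,6,5.46,5.93,9,12.57,5.47,-56
6,2.54,2.50,-2,9.28,8.80,-5,11.87,9.91,-16
7,1.37,1.48,8,4.49,5.72,27,23.39,13.09,-44
8,1.35,1.47,9,4.43,5.80,31,16.43,12.62,-23
10,1.54,1.76,14,5.06,6.13,21,10.07,9.43,-6
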