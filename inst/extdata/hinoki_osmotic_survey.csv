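date,doy,time_class,position,t_a_min,t_a_max,vpd_max,r_g,water_content_mean,water_content_sd,osmolality_mean,osmolality_sd,pressure_mean,pressure_sd
2019-08-07,219,dawn,upper,25.5,34.7,2.93,24.5,1.5,0.2,0.47,0.03,1.16,0.05
2019-08-07,219,dawn,lower,25.5,34.7,2.93,24.5,1.3,0.2,0.41,0.05,1.02,0.08
2019-08-07,219,early_afternoon,upper,25.5,34.7,2.93,24.5,1.5,0.1,0.44,0.06,0.07,0.05
2019-08-07,219,early_afternoon,lower,25.5,34.7,2.93,24.5,1.4,0.2,0.37,0.03,0.10,0.05
2019-09-02,245,dawn,upper,21.6,32.7,2.48,17.9,1.4,0.2,0.44,0.06,1.05,0.09
2019-09-02,245,dawn,lower,21.6,32.7,2.48,17.9,1.4,0.3,0.36,0.08,0.89,0.12
2019-09-02,245,early_afternoon,upper,21.6,32.7,2.48,17.9,1.4,0.2,0.48,0.01,0.35,0.07
2019-09-02,245,early_afternoon,lower,21.6,32.7,2.48,17.9,1.5,0.3,0.41,0.06,0.42,0.04
2019-12-12,346,dawn,upper,4.1,11.1,0.73,4.7,1.2,0.1,0.60,0.07,1.50,0.18
2019-12-12,346,dawn,lower,4.1,11.1,0.73,4.7,1.4,0.3,0.47,0.04,1.16,0.09
2019-12-12,346,early_afternoon,upper,4.1,11.1,0.73,4.7,1.2,0.1,0.62,0.13,1.13,0.31
2019-12-12,346,early_afternoon,lower,4.1,11.1,0.73,4.7,1.3,0.2,0.48,0.06,0.88,0.21
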