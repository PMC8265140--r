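variable,level,coefficient,elasticity,ci,contribution,pct,group_pct
age,20-29,-0.360,-0.020,0.010,0.000,0.7,0.4
age,30-39,-0.240,-0.012,-0.002,0.000,-0.1,0.4
age,40-49,-0.042,-0.003,0.016,0.000,0.2,0.4
age,50-54,0.179,0.003,0.043,0.000,-0.4,0.4
marital,currently_married,-0.013,0.001,-0.013,0.000,0.0,0.0
education,primary,-0.102,-0.003,-0.278,0.001,-3.3,14.6
education,secondary,-0.184,-0.019,0.030,-0.001,2.0,14.6
education,higher,-0.349,-0.010,0.440,-0.005,15.8,14.6
media,exposure,-0.068,-0.014,0.054,-0.001,2.7,2.7
bmi,underweight,0.411,0.016,-0.219,-0.003,11.9,17.8
bmi,overweight,-0.222,-0.006,0.309,-0.002,5.9,17.8
tobacco,yes,-0.079,-0.004,-0.149,0.001,-2.2,-2.2
caste,scheduled_caste,-0.036,0.001,-0.157,0.000,0.3,8.6
caste,scheduled_tribe,0.283,0.006,-0.420,-0.002,8.4,8.6
caste,obc,-0.036,0.001,0.014,0.000,-0.1,8.6
religion,muslim,-0.130,-0.003,0.038,0.000,0.3,-0.4
religion,other,-0.033,0.001,0.229,0.000,-0.7,-0.4
residence,rural,0.115,0.016,-0.230,-0.004,12.6,12.6
wealth,poorer,-0.107,-0.003,-0.512,0.002,-5.9,25.1
wealth,middle,-0.187,-0.006,-0.110,0.001,-2.4,25.1
wealth,richer,-0.253,-0.008,0.323,-0.003,8.8,25.1
wealth,richest,-0.287,-0.009,0.772,-0.007,24.6,25.1
region,central,0.012,0.003,-0.161,-0.001,1.9,20.9
region,east,0.334,0.015,-0.339,-0.005,17.9,20.9
region,northeast,-0.294,0.000,-0.253,0.000,0.4,20.9
region,west,-0.134,-0.002,0.156,0.000,1.1,20.9
region,south,-0.070,0.001,0.186,0.000,-0.3,20.9
footer,calculated_ci,NA,NA,NA,-0.029,NA,NA
footer,actual_ci,NA,NA,NA,-0.121,NA,NA
footer,residual,NA,NA,NA,-0.092,NA,NA
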