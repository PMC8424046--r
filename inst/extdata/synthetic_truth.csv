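peak,mu,sigma,f_E1,f_E2,f_E3,w0,w_temperature_mean,w_temperature_sd,w_humidity_mean,w_humidity_sd,w_light_mean,w_light_sd,w_soil_moisture_mean,w_soil_moisture_sd,w_soil_ph_mean,w_soil_ph_sd
1,1.395,0.09,1,0.61,0.602,0.985,0.447,0.011,-0.393,-0.93,0.014,0.348,-0.173,0.028,0.478,0.596
2,3.078,0.169,1,0.581,0.842,0.284,-0.351,-0.96,-0.654,-0.484,0.364,0.364,0.193,0.388,0.149,0.109
3,4.633,0.092,1,0.64,0.596,0.878,0.059,0.45,0.306,0.097,0.551,0.271,-0.547,-0.046,0.1,-0.389
4,6.15,0.085,1,0.954,0.385,1.213,0.343,-0.054,-0.051,-0.071,0.624,-0.229,0.533,0.095,0.1,-0.035
5,7.685,0.124,1,0.807,0.668,0.975,0.073,-0.258,0.22,0.275,0.355,-0.372,-0.554,0.15,0.205,0.23
6,9.2,0.107,1,0.703,0.353,0.666,0.018,-0.251,0.017,0.858,0.211,-0.044,-0.463,-0.299,0.317,0.081
7,10.907,0.094,1,0.9,0.866,0.498,-0.416,0.304,-0.236,0.204,-0.178,0.052,-0.467,0.3,-0.187,0.054
8,12.581,0.2,1,0.998,0.522,1.056,0.319,-0.141,0.526,0.572,0.043,-0.429,0.212,0.092,0.18,0.554
9,13.828,0.184,1,0.528,0.633,0.644,0.357,-0.092,-0.412,0.34,-0.592,0.208,-0.512,0.196,0.407,-0.152
10,15.343,0.115,1,0.832,0.899,0.513,-0.034,0.122,-0.145,0.032,0.181,-0.536,0.129,-0.241,0.343,-0.077
11,16.872,0.133,1,0.556,0.318,1.261,0,-0.511,0.088,0.157,0.451,0.199,-0.167,-0.098,0.535,0.076
12,18.543,0.095,1,0.7,0.78,0.823,0.16,0.126,-0.338,0.668,0.048,0.455,0.036,-0.26,0.107,0.198
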