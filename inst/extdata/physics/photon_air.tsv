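# Photon mass attenuation (mu/rho, with coherent) and mass energy-
# absorption (muen/rho) coefficients for dry air, cm^2/g,
# XCOM/NIST-style tabulation, log-log interpolated at use.
energy_keV	mu_rho_cm2_g	muen_rho_cm2_g
10	5.12	4.742
15	1.614	1.334
20	0.7779	0.5389
30	0.3538	0.1537
40	0.2485	0.06833
50	0.208	0.04098
60	0.1875	0.03041
80	0.1662	0.02407
100	0.1541	0.02325
150	0.1356	0.02496
200	0.1233	0.02672
300	0.1067	0.02872
400	0.09549	0.02949
500	0.08712	0.02966
600	0.08055	0.02953
800	0.07074	0.02882
1000	0.06358	0.02789
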