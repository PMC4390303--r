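# Photon mass attenuation (mu/rho, with coherent) and mass energy-
# absorption (muen/rho) coefficients for polypropylene (C3H6)n, cm^2/g,
# XCOM/NIST-style tabulation, log-log interpolated at use.
# built by the elemental mixture rule, mass fractions H 0.1437, C 0.8563.
energy_keV	mu_rho_cm2_g	muen_rho_cm2_g
10	2.08738	1.78081
15	0.745208	0.483421
20	0.431582	0.193551
30	0.270685	0.0593085
40	0.227459	0.0319456
50	0.208425	0.0244198
60	0.196956	0.022348
80	0.182282	0.0226448
100	0.171949	0.024219
150	0.153438	0.0279402
200	0.140144	0.0303509
300	0.121631	0.0328098
400	0.108945	0.033696
500	0.0994723	0.0338875
600	0.0919783	0.0337618
800	0.0807816	0.0329383
1000	0.0726186	0.0318832
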