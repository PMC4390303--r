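# Electron CSDA range in liquid water (ESTAR/NIST-style tabulation)
# used as the soft-tissue surrogate for blood and, with density
# scaling, for the polypropylene wall.
energy_keV	csda_range_g_cm2
10	0.0002515
15	0.0005147
20	0.0008566
30	0.001756
40	0.002907
50	0.004285
60	0.005874
80	0.009657
100	0.01431
150	0.02817
200	0.04488
300	0.08421
400	0.128
500	0.1756
600	0.2248
800	0.3269
1000	0.4367
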