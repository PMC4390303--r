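# Lu-177 decay data, curated from the ICRP Publication 107 / Eckerman & Endo
# electronic tabulation: allowed-shape beta spectra rebinned to 5 keV,
# conversion and Auger electrons, gamma and X-ray lines.
# Sub-keV Auger electrons and sub-10-keV photons lumped into single lines.
# half_life_days: 6.6470
kind	energy_keV	yield_per_decay
beta_spectrum_bin	2.5	0.0275982
beta_spectrum_bin	7.5	0.0271381
beta_spectrum_bin	12.5	0.0266717
beta_spectrum_bin	17.5	0.0261995
beta_spectrum_bin	22.5	0.025722
beta_spectrum_bin	27.5	0.0252402
beta_spectrum_bin	32.5	0.0247545
beta_spectrum_bin	37.5	0.0242659
beta_spectrum_bin	42.5	0.023775
beta_spectrum_bin	47.5	0.0232827
beta_spectrum_bin	52.5	0.0227895
beta_spectrum_bin	57.5	0.0222963
beta_spectrum_bin	62.5	0.0218038
beta_spectrum_bin	67.5	0.0213126
beta_spectrum_bin	72.5	0.0208235
beta_spectrum_bin	77.5	0.0203372
beta_spectrum_bin	82.5	0.0198545
beta_spectrum_bin	87.5	0.0193759
beta_spectrum_bin	92.5	0.0189023
beta_spectrum_bin	97.5	0.0184344
beta_spectrum_bin	102.5	0.017973
beta_spectrum_bin	107.5	0.0175187
beta_spectrum_bin	112.5	0.0170725
beta_spectrum_bin	117.5	0.0166351
beta_spectrum_bin	122.5	0.0162072
beta_spectrum_bin	127.5	0.0157897
beta_spectrum_bin	132.5	0.0153835
beta_spectrum_bin	137.5	0.0149893
beta_spectrum_bin	142.5	0.0146081
beta_spectrum_bin	147.5	0.0142406
beta_spectrum_bin	152.5	0.0138877
beta_spectrum_bin	157.5	0.0135505
beta_spectrum_bin	162.5	0.0132296
beta_spectrum_bin	167.5	0.0129262
beta_spectrum_bin	172.5	0.012641
beta_spectrum_bin	177.5	0.0123743
beta_spectrum_bin	182.5	0.0121148
beta_spectrum_bin	187.5	0.0118537
beta_spectrum_bin	192.5	0.0115907
beta_spectrum_bin	197.5	0.0113262
beta_spectrum_bin	202.5	0.0110603
beta_spectrum_bin	207.5	0.0107931
beta_spectrum_bin	212.5	0.0105249
beta_spectrum_bin	217.5	0.0102558
beta_spectrum_bin	222.5	0.00998601
beta_spectrum_bin	227.5	0.0097157
beta_spectrum_bin	232.5	0.00944508
beta_spectrum_bin	237.5	0.00917432
beta_spectrum_bin	242.5	0.00890364
beta_spectrum_bin	247.5	0.00863324
beta_spectrum_bin	252.5	0.00836331
beta_spectrum_bin	257.5	0.00809406
beta_spectrum_bin	262.5	0.0078257
beta_spectrum_bin	267.5	0.00755844
beta_spectrum_bin	272.5	0.00729249
beta_spectrum_bin	277.5	0.00702808
beta_spectrum_bin	282.5	0.00676542
beta_spectrum_bin	287.5	0.00650474
beta_spectrum_bin	292.5	0.00624625
beta_spectrum_bin	297.5	0.0059902
beta_spectrum_bin	302.5	0.00573681
beta_spectrum_bin	307.5	0.00548631
beta_spectrum_bin	312.5	0.00523894
beta_spectrum_bin	317.5	0.00499495
beta_spectrum_bin	322.5	0.00475456
beta_spectrum_bin	327.5	0.00451803
beta_spectrum_bin	332.5	0.00428561
beta_spectrum_bin	337.5	0.00405754
beta_spectrum_bin	342.5	0.00383408
beta_spectrum_bin	347.5	0.00361547
beta_spectrum_bin	352.5	0.00340199
beta_spectrum_bin	357.5	0.00319388
beta_spectrum_bin	362.5	0.00299142
beta_spectrum_bin	367.5	0.00279487
beta_spectrum_bin	372.5	0.00260449
beta_spectrum_bin	377.5	0.00242055
beta_spectrum_bin	382.5	0.00224333
beta_spectrum_bin	387.5	0.0020728
beta_spectrum_bin	392.5	0.00190772
beta_spectrum_bin	397.5	0.00174787
beta_spectrum_bin	402.5	0.00159347
beta_spectrum_bin	407.5	0.00144474
beta_spectrum_bin	412.5	0.0013019
beta_spectrum_bin	417.5	0.00116518
beta_spectrum_bin	422.5	0.0010348
beta_spectrum_bin	427.5	0.000911001
beta_spectrum_bin	432.5	0.000794002
beta_spectrum_bin	437.5	0.000684041
beta_spectrum_bin	442.5	0.000581349
beta_spectrum_bin	447.5	0.000486166
beta_spectrum_bin	452.5	0.000398727
beta_spectrum_bin	457.5	0.000319274
beta_spectrum_bin	462.5	0.000248049
beta_spectrum_bin	467.5	0.000185295
beta_spectrum_bin	472.5	0.000131258
beta_spectrum_bin	477.5	8.61854e-05
beta_spectrum_bin	482.5	5.03269e-05
beta_spectrum_bin	487.5	2.39338e-05
beta_spectrum_bin	492.5	7.25898e-06
beta_spectrum_bin	497.5	4.90113e-07
conversion_or_auger	6.2	0.076
conversion_or_auger	39.8	0.004
conversion_or_auger	47.6	0.076
conversion_or_auger	103.5	0.046
conversion_or_auger	111.2	0.017
conversion_or_auger	143	0.0053
conversion_or_auger	198.4	0.0012
photon	7.9	0.027
photon	55.8	0.056
photon	63.2	0.013
photon	112.95	0.062
photon	136.7	0.00047
photon	208.4	0.104
photon	249.7	0.0021
photon	321.3	0.0022
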