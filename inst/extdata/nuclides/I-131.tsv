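# I-131 decay data, curated from the ICRP Publication 107 / Eckerman & Endo
# electronic tabulation: allowed-shape beta spectra rebinned to 5 keV,
# conversion and Auger electrons, gamma and X-ray lines.
# Sub-keV Auger electrons and sub-10-keV photons lumped into single lines.
# half_life_days: 8.0230
kind	energy_keV	yield_per_decay
beta_spectrum_bin	2.5	0.0173367
beta_spectrum_bin	7.5	0.0172721
beta_spectrum_bin	12.5	0.0172018
beta_spectrum_bin	17.5	0.0171259
beta_spectrum_bin	22.5	0.0170451
beta_spectrum_bin	27.5	0.0169601
beta_spectrum_bin	32.5	0.016871
beta_spectrum_bin	37.5	0.0167782
beta_spectrum_bin	42.5	0.0166819
beta_spectrum_bin	47.5	0.0165819
beta_spectrum_bin	52.5	0.0164784
beta_spectrum_bin	57.5	0.0163713
beta_spectrum_bin	62.5	0.0162605
beta_spectrum_bin	67.5	0.0161461
beta_spectrum_bin	72.5	0.0160281
beta_spectrum_bin	77.5	0.0159064
beta_spectrum_bin	82.5	0.015781
beta_spectrum_bin	87.5	0.0156519
beta_spectrum_bin	92.5	0.0155192
beta_spectrum_bin	97.5	0.0153828
beta_spectrum_bin	102.5	0.0152428
beta_spectrum_bin	107.5	0.0150993
beta_spectrum_bin	112.5	0.0149524
beta_spectrum_bin	117.5	0.014802
beta_spectrum_bin	122.5	0.0146484
beta_spectrum_bin	127.5	0.0144915
beta_spectrum_bin	132.5	0.0143315
beta_spectrum_bin	137.5	0.0141685
beta_spectrum_bin	142.5	0.0140025
beta_spectrum_bin	147.5	0.0138338
beta_spectrum_bin	152.5	0.0136625
beta_spectrum_bin	157.5	0.0134886
beta_spectrum_bin	162.5	0.0133123
beta_spectrum_bin	167.5	0.0131338
beta_spectrum_bin	172.5	0.0129533
beta_spectrum_bin	177.5	0.0127708
beta_spectrum_bin	182.5	0.0125865
beta_spectrum_bin	187.5	0.0124007
beta_spectrum_bin	192.5	0.0122134
beta_spectrum_bin	197.5	0.0120249
beta_spectrum_bin	202.5	0.0118354
beta_spectrum_bin	207.5	0.011645
beta_spectrum_bin	212.5	0.0114539
beta_spectrum_bin	217.5	0.0112623
beta_spectrum_bin	222.5	0.0110705
beta_spectrum_bin	227.5	0.0108786
beta_spectrum_bin	232.5	0.0106868
beta_spectrum_bin	237.5	0.0104953
beta_spectrum_bin	242.5	0.0103045
beta_spectrum_bin	247.5	0.0101144
beta_spectrum_bin	252.5	0.00992449
beta_spectrum_bin	257.5	0.00973417
beta_spectrum_bin	262.5	0.00954348
beta_spectrum_bin	267.5	0.00935262
beta_spectrum_bin	272.5	0.00916174
beta_spectrum_bin	277.5	0.00897103
beta_spectrum_bin	282.5	0.00878067
beta_spectrum_bin	287.5	0.00859084
beta_spectrum_bin	292.5	0.00840173
beta_spectrum_bin	297.5	0.00821353
beta_spectrum_bin	302.5	0.00802643
beta_spectrum_bin	307.5	0.00784053
beta_spectrum_bin	312.5	0.00765582
beta_spectrum_bin	317.5	0.00747248
beta_spectrum_bin	322.5	0.00729068
beta_spectrum_bin	327.5	0.00711064
beta_spectrum_bin	332.5	0.00693253
beta_spectrum_bin	337.5	0.0067557
beta_spectrum_bin	342.5	0.00657859
beta_spectrum_bin	347.5	0.0064011
beta_spectrum_bin	352.5	0.00622335
beta_spectrum_bin	357.5	0.00604546
beta_spectrum_bin	362.5	0.00586754
beta_spectrum_bin	367.5	0.00568971
beta_spectrum_bin	372.5	0.0055121
beta_spectrum_bin	377.5	0.00533483
beta_spectrum_bin	382.5	0.00515801
beta_spectrum_bin	387.5	0.00498179
beta_spectrum_bin	392.5	0.00480628
beta_spectrum_bin	397.5	0.00463161
beta_spectrum_bin	402.5	0.00445792
beta_spectrum_bin	407.5	0.00428533
beta_spectrum_bin	412.5	0.00411398
beta_spectrum_bin	417.5	0.00394401
beta_spectrum_bin	422.5	0.00377555
beta_spectrum_bin	427.5	0.00360875
beta_spectrum_bin	432.5	0.00344373
beta_spectrum_bin	437.5	0.00328065
beta_spectrum_bin	442.5	0.00311965
beta_spectrum_bin	447.5	0.00296087
beta_spectrum_bin	452.5	0.00280445
beta_spectrum_bin	457.5	0.00265056
beta_spectrum_bin	462.5	0.00249933
beta_spectrum_bin	467.5	0.00235091
beta_spectrum_bin	472.5	0.00220547
beta_spectrum_bin	477.5	0.00206315
beta_spectrum_bin	482.5	0.00192411
beta_spectrum_bin	487.5	0.0017885
beta_spectrum_bin	492.5	0.00165649
beta_spectrum_bin	497.5	0.00152824
beta_spectrum_bin	502.5	0.00140391
beta_spectrum_bin	507.5	0.00128366
beta_spectrum_bin	512.5	0.00116765
beta_spectrum_bin	517.5	0.00105605
beta_spectrum_bin	522.5	0.00094904
beta_spectrum_bin	527.5	0.000846775
beta_spectrum_bin	532.5	0.000749431
beta_spectrum_bin	537.5	0.000657181
beta_spectrum_bin	542.5	0.000570197
beta_spectrum_bin	547.5	0.000488656
beta_spectrum_bin	552.5	0.000412734
beta_spectrum_bin	557.5	0.000342609
beta_spectrum_bin	562.5	0.000278463
beta_spectrum_bin	567.5	0.000220475
beta_spectrum_bin	572.5	0.000168829
beta_spectrum_bin	577.5	0.00012371
beta_spectrum_bin	582.5	8.53021e-05
beta_spectrum_bin	587.5	5.37939e-05
beta_spectrum_bin	592.5	2.93739e-05
beta_spectrum_bin	597.5	1.22323e-05
beta_spectrum_bin	602.5	2.56087e-06
beta_spectrum_bin	607.5	2.28439e-08
conversion_or_auger	3.4	0.051
conversion_or_auger	24.6	0.006
conversion_or_auger	45.6	0.0354
conversion_or_auger	74.7	0.0046
conversion_or_auger	249.7	0.0025
conversion_or_auger	329.9	0.0155
conversion_or_auger	359.7	0.0025
conversion_or_auger	363.6	0.00055
photon	4.1	0.008
photon	29.7	0.039
photon	33.6	0.009
photon	80.19	0.0262
photon	284.3	0.0612
photon	325.8	0.0027
photon	364.5	0.812
photon	503	0.0036
photon	637	0.0716
photon	642.7	0.0022
photon	722.9	0.0177
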