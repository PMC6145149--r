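#dataset=species-level structome summary statistics
#provenance=published summary values (n, mean, sample SD) for microorganisms profiled by serial ultrathin-section structome analysis
#units=diameters um; surfaces um2; volumes fl; ribosome_density per 0.1 fl cytoplasm
group	metric	n	mean	sd
Myojin spiral bacteria	ribosomes_total	6	320	120
Myojin spiral bacteria	vol_cytoplasm	6	0.18	0.07
Myojin spiral bacteria	ribosome_density	6	220	120
Myojin amorphous bacteria	ribosomes_total	10	1150	370
Myojin amorphous bacteria	vol_cytoplasm	10	0.37	0.09
Myojin amorphous bacteria	ribosome_density	10	310	40
M. tuberculosis	ribosomes_total	5	1670	570
M. tuberculosis	vol_cytoplasm	5	0.21	0.09
M. tuberculosis	ribosome_density	5	720	170
M. tuberculosis	diam_om	5	0.34	0.03
M. tuberculosis	diam_pm	5	0.30	0.02
M. tuberculosis	surf_om	5	3.03	1.33
M. tuberculosis	surf_pm	5	2.67	1.19
M. tuberculosis	vol_whole	5	0.29	0.11
M. tuberculosis	aspect_ratio	5	8.24	3.61
M. smegmatis	ribosomes_total	7	8670	2660
M. smegmatis	vol_cytoplasm	7	0.77	0.31
M. smegmatis	ribosome_density	7	1170	180
E. coli	ribosomes_total	9	26120	4000
E. coli	vol_cytoplasm	9	0.90	0.16
E. coli	ribosome_density	9	2840	120
E. coli	diam_om	9	0.89	0.06
E. coli	aspect_ratio	9	2.84	0.46
E. dermatitidis	ribosomes_total	5	195000	91100
E. dermatitidis	vol_cytoplasm	5	17.1	6.3
E. dermatitidis	ribosome_density	5	1100	150
S. cerevisiae	ribosomes_total	6	195000	54800
S. cerevisiae	vol_cytoplasm	6	10.0	2.6
S. cerevisiae	ribosome_density	6	1950	100
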