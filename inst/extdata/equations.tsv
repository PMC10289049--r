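id	label	family	k	a_tc	a_hdl	a_tg	a_tg2	a_tgnonhdl	a0	table	tg_lo	tg_hi	source_units	provenance	citation
friedewald	Friedewald	fixed_ratio	5	NA	NA	NA	NA	NA	NA	NA	0	400	mg/dL	transcribed	Friedewald et al. 1972, Clin Chem 18:499-502
puavilai	Puavilai	fixed_ratio	6	NA	NA	NA	NA	NA	NA	NA	0	400	mg/dL	transcribed	Puavilai et al. 2009, J Med Assoc Thai
vujovic	Vujovic	fixed_ratio	6.85	NA	NA	NA	NA	NA	NA	NA	0	400	mg/dL	transcribed	Vujovic et al. 2010, Lipids Health Dis 9:27
delong	DeLong	fixed_ratio	6.25	NA	NA	NA	NA	NA	NA	NA	0	400	mg/dL	transcribed	DeLong et al. 1986, JAMA 256:2372-2377 (VLDL-C = 0.16 x TG)
ephraim	Ephraim	fixed_ratio	8.5	NA	NA	NA	NA	NA	NA	NA	0	400	mg/dL	reconstructed	Ephraim et al. 2018
ghasemi	Ghasemi	fixed_ratio	4	NA	NA	NA	NA	NA	NA	NA	0	400	mg/dL	reconstructed	Ghasemi et al. 2018
bauer	Bauer	fixed_ratio	7.5	NA	NA	NA	NA	NA	NA	NA	0	400	mg/dL	reconstructed	Bauer et al. 2013
hattori	Hattori	linear	NA	0.94	-0.94	-0.19	NA	NA	0	NA	0	400	mg/dL	transcribed	Hattori et al. 1998, Atherosclerosis 138:289-299
anandaraja	Anandaraja	linear	NA	0.9	0	-0.18	NA	NA	-28	NA	0	400	mg/dL	transcribed	Anandaraja et al. 2005, Int J Cardiol 102:117-120
chen	Chen	linear	NA	0.9	-0.9	-0.1	NA	NA	0	NA	0	400	mg/dL	transcribed	Chen et al. 2010, Lipids Health Dis 9:52
cordova	Cordova	linear	NA	0.75	-0.75	0	NA	NA	0	NA	0	400	mg/dL	transcribed	de Cordova & de Cordova 2013, Ann Clin Biochem 50:13-19
teerakanchana	Teerakanchana	linear	NA	0.89	-0.774	-0.163	NA	NA	11.57	NA	0	400	mg/dL	transcribed	Teerakanchana et al. 2007, J Med Assoc Thai 90:2250-2257
ahmadi	Ahmadi	linear	NA	0.8403361344537815	-0.9090909090909091	0.5263157894736842	NA	NA	-38	NA	0	400	mg/dL	transcribed	Ahmadi et al. 2008, Arch Iran Med 11:318-321 (TC/1.19 + TG/1.9 - HDL/1.1 - 38)
rao	Rao	linear	NA	1.07	-1.07	-0.214	NA	NA	0	NA	0	400	mg/dL	reconstructed	Rao et al. 1988
dansethakul	Dansethakul	linear	NA	1	-1	-0.2	NA	NA	7.1	NA	0	400	mg/dL	reconstructed	Dansethakul et al. 2015
rasouli	Rasouli	linear	NA	0.91	-0.91	-0.182	NA	NA	0	NA	0	400	mg/dL	reconstructed	Rasouli et al.
lee_hu	Lee and Hu	linear	NA	0.9	0	-0.18	NA	NA	-30	NA	0	400	mg/dL	reconstructed	Lee & Hu
choi	Choi	linear	NA	1.13	-1.13	-0.226	NA	NA	0	NA	0	400	mg/dL	reconstructed	Choi et al.
orejon	Orejon	linear	NA	1.055	-1.055	-0.211	NA	NA	0	NA	0	400	mg/dL	reconstructed	Orejon et al.
molavi	Molavi	linear	NA	1	-1	-0.2	NA	NA	-0.9	NA	0	400	mg/dL	reconstructed	Molavi et al.
sampson	Sampson	quadratic	NA	1.0548523206751055	-1.0298661174047375	-0.11682242990654206	6.211180124223602e-05	-0.00046728971962616824	-9.44	NA	0	800	mg/dL	transcribed	Sampson et al. 2020, JAMA Cardiol 5:540-548 (TC/0.948 - HDL/0.971 - TG/8.56 - TG*nonHDL/2140 + TG^2/16100 - 9.44)
saiedullah	Saiedullah	quadratic	NA	1	-1	-0.2	-0.00028571428571428574	0	0	NA	0	400	mg/dL	reconstructed	Saiedullah et al.
martin_hopkins	Martin/Hopkins	table_factor	NA	NA	NA	NA	NA	NA	NA	standard	0	400	mg/dL	transcribed	Martin et al. 2013, JAMA 310:2061-2068
martin_hopkins_extended	Martin/Hopkins extended	table_factor	NA	NA	NA	NA	NA	NA	NA	extended	400	800	mg/dL	transcribed	Sathiyakumar et al. 2020 (factor row from Martin et al. 2013 TG>=400 stratum)
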