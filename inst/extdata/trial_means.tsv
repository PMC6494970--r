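# Printed trait means of the F271 x Cm484 maize trial under irrigated (I)
# and non-irrigated (NI) scenarios: the two parental inbred lines and the
# RIL-progeny average for plant height. Inputs for percent-response
# recomputation.
group	line	trait	mean_I	mean_NI
parent	F271	plant_height_cm	172.08	143.52
parent	Cm484	plant_height_cm	134.06	122.91
parent	F271	yield_t_ha	3.83	2.43
parent	Cm484	yield_t_ha	2.48	2.09
parent	F271	IVDMD_pct	46.78	50.95
parent	Cm484	IVDMD_pct	55.68	56.28
parent	F271	IVCWRD_pct	30.11	38.16
parent	Cm484	IVCWRD_pct	36.49	43.19
ril_progeny	all	plant_height_cm	149.18	127.07
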