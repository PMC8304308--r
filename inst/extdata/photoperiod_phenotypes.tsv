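# First-flower phenotypes of the photoperiod-sensitive XIS cucumber
# accession SWCC8 under two light-dark cycles: short day (SD, 8 h light /
# 16 h dark) and equal day (ED, 12 h / 12 h). One row per treatment;
# values are means over replicate plants at first male flower opening.
treatment	day_night	dff_days	dff_sd	nff_nodes	height_cm
SD	8h/16h	80.0	0.0	11.3	55.5
ED	12h/12h	98.0	0.0	16.0	68.2
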