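build	n_gaps_ge2kb	n_gaps_intersected	n_discordances	n_disc_intersecting	n_gaps_bridged	printed_gap_pct	printed_disc_pct	tel_ext_total_kb	n_chr_ends_extended
UMD3.1	606	167	4754	162	584	27.6	3.4	19135	50
Btau4.6	5450	4586	7463	3801	5401	84.2	50.8	38346	55
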