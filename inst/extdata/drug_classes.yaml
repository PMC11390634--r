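# Antihypertensive drug classes (British National Formulary grouping) and
# the genes encoding their pharmacological targets. Static curated map;
# users may supply their own YAML in the same shape.
adrenergic_neuron_blockers: [SLC6A2]
alpha_adrenoceptor_blockers: [ADRA1A, ADRA1B, ADRA1D]
angiotensin_ii_receptor_antagonists: [AGTR1]
ace_inhibitors: [ACE]
beta_blockers: [ADRB1, ADRB2]
calcium_channel_blockers: [CACNA1C, CACNA1D, CACNA2D1]
centrally_acting_antihypertensives: [ADRA2A, ADRA2B, ADRA2C]
loop_diuretics: [SLC12A1]
psd_aldosterone_antagonists: [NR3C2, SCNN1A, SCNN1B, SCNN1G]
renin_inhibitors: [REN]
thiazide_diuretics: [SLC12A3]
vasodilator_antihypertensives: [ABCC9, KCNJ8]
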