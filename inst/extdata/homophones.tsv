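word_a	word_b	expected_same_sound
kollesterraulle	cholesterol	1
alzaymer	alzheimer	1
kancer	cancer	1
fisioterapie	physiotherapie	1
foi	foie	1
sirop	sirops	1
otite	ottite	1
ekzema	eczema	1
asme	asthme	1
grype	grippe	1
insomnia	innsomnia	1
androstenes	androstenols	0
asthma	hepatite	0
ammidale	amygdale	0
insomnia	inosine	0
rickttsiose	rickettsioses	0
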