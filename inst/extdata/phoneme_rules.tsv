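tier	pattern	before	after	position	replacement	minlen	confidence
pre	ill			any	6	0	high
pre	y			any	i	0	high
pre	omac			end	oma	0	high
pre	irops			end	iro	0	high
pre	irop			end	iro	0	high
pre	stme			end	sm	0	high
pre	ac			end	a	4	high
context	ain		!aeioun1234680	any	1	0	high
context	ein		!aeioun1234680	any	1	0	high
context	eim		!aeioum1234680	any	1	0	high
context	oin		!aeioun1234680	any	0	0	high
context	an		!aeioun1234680	any	4	0	high
context	am		!aeiounm12346780	any	4	0	high
context	en		!aeioun1234680	any	4	0	high
context	em		!aeioum1234680	any	4	0	high
context	in	!oea	!aeioun1234680	any	1	0	high
context	im	!oea	!aeioum1234680	any	1	0	high
context	un		!aeioun1234680	any	1	0	high
context	ge		ao2340	any	g	0	high
context	gu		ei124680	any	g	0	high
subst	thm			any	m	0	high
subst	sch			any	5	0	high
subst	ch			any	5	0	high
subst	sh			any	5	0	high
subst	5o			any	ko	0	high
subst	5l			any	kl	0	high
subst	5r			any	kr	0	high
subst	5t			any	kt	0	high
subst	ph			any	f	0	high
subst	qu			any	k	0	high
subst	gn			any	7	0	high
subst	ptio			any	psio	0	high
subst	tion			any	sion	0	high
subst	x			any	ks	0	high
subst	eau			any	o	0	high
subst	au			any	o	0	high
subst	oeu			any	8	0	high
subst	ai			any	8	0	high
subst	ei			any	8	0	high
subst	oi			any	2	0	high
subst	ou			any	3	0	high
subst	h			any		0	high
subst	c			any	k	0	high
subst	q			any	k	0	high
subst	l1			any	l8n	0	low
subst	u			any	o	0	low
subst	r0			any	ro1	0	low
subst	31			any	0	0	low
subst	8mm			any	am	0	low
subst	am7			any	ami	0	low
subst	si5			any	sik	0	low
subst	o6			any	26	0	low
subst	oz1			any	os1	0	low
subst	s			any	ss	0	low
subst	ati4			any	assi4	0	low
final	s			end		3	high
final	e			end		3	high
final	g	012345678		end		0	high
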