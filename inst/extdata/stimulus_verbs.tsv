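experiment	language	infinitive	verb_type	form_1st	form_2nd	form_3rd	english
exp1	italian	afferrare	AV	io afferravo	tu afferravi	egli afferrava	to grasp
exp1	italian	alzare	AV	io alzavo	tu alzavi	egli alzava	to raise
exp1	italian	portare	AV	io portavo	tu portavi	egli portava	to carry
exp1	italian	prendere	AV	io prendevo	tu prendevi	egli prendeva	to take
exp1	italian	sollevare	AV	io sollevavo	tu sollevavi	egli sollevava	to lift up
exp1	italian	consegnare	IV	io consegnavo	tu consegnavi	egli consegnava	to deliver
exp1	italian	dare	IV	io davo	tu davi	egli dava	to give
exp1	italian	offrire	IV	io offrivo	tu offrivi	egli offriva	to offer
exp1	italian	porgere	IV	io porgevo	tu porgevi	egli porgeva	to hand
exp1	italian	scambiare	IV	io scambiavo	tu scambiavi	egli scambiava	to exchange
exp2	german	packen	AV	ich packe	du packst	er packt	to pack
exp2	german	greifen	AV	ich greife	du greifst	er greift	to grasp
exp2	german	heben	AV	ich hebe	du hebst	er hebt	to lift
exp2	german	holen	AV	ich hole	du holst	er holt	to get
exp2	german	ergreifen	AV	ich ergreife	du ergreifst	er ergreift	to seize
exp2	german	schnappen	AV	ich schnappe	du schnappst	er schnappt	to grab
exp2	german	fassen	AV	ich fasse	du fasst	er fasst	to take
exp2	german	bringen	IV	ich bringe	du bringst	er bringt	to bring
exp2	german	reichen	IV	ich reiche	du reichst	er reicht	to hand
exp2	german	liefern	IV	ich liefere	du lieferst	er liefert	to supply
exp2	german	tauschen	IV	ich tausche	du tauschst	er tauscht	to exchange
exp2	german	geben	IV	ich gebe	du gibst	er gibt	to give
exp2	german	bieten	IV	ich biete	du bietest	er bietet	to offer
exp2	german	stiften	IV	ich stifte	du stiftest	er stiftet	to donate
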