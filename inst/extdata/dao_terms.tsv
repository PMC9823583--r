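concept_id	surface	term_type	case_sensitive
Buprenorphine	Suboxone	brand	0
Buprenorphine	Subutex	brand	0
Buprenorphine	Bupe	slang	0
Buprenorphine	Bupey	slang	0
Fentanyl	Duragesic	brand	0
Fentanyl	china white	street	0
Fentanyl	synthetic heroine	street	0
Fluoro_Furanyl_Fentanyl	fuff	abbreviation	0
Poppy_Tea	Pod	slang	0
Poppy_Tea	Poppy_Pods	slang	0
Cannabis	marijuana	street	0
Finalize_Early	FE	abbreviation	1
Injection	injected	synonym	0
Injection	inject	synonym	0
Insufflation	snorted	synonym	0
Insufflation	snort	synonym	0
Anxiety	antsy	lay_term	0
Anxiety	worried	lay_term	0
Anxiety	agitated	lay_term	0
Anxiety	anxious	synonym	0
Cannabis_Use_Disorder	addicted to cannabis	lay_term	0
Cannabis_Use_Disorder	addicted to Marijuana	lay_term	0
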