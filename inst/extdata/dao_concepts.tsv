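id	label	kind	parent_id
Opioid	opioid	substance_class
Cannabinoid	cannabinoid	substance_class
Fentanyl_Type	fentanyl-type	substance_class	Opioid
Other_NP_Synthetic_Opioid	other NP synthetic opioids	substance_class	Opioid
Fentanyl	fentanyl	substance_class	Fentanyl_Type
Acetyl_Fentanyl	acetyl fentanyl	substance_class	Fentanyl_Type
Butyr_Fentanyl	butyr fentanyl	substance_class	Fentanyl_Type
Carfentanil	carfentanil	substance_class	Fentanyl_Type
Furanyl_Fentanyl	furanyl fentanyl	substance_class	Fentanyl_Type
Methoxy_Acetyl_Fentanyl	methoxy acetyl fentanyl	substance_class	Fentanyl_Type
FluroIsoButyr_Fentanyl	4-fluroIsoButyr fentanyl	substance_class	Fentanyl_Type
MethoxyMethyl_Fentanyl	3-methoxyMethyl fentanyl	substance_class	Fentanyl_Type
Fluoro_Furanyl_Fentanyl	fluoro-furanyl fentanyl	substance_class	Fentanyl_Type
U_47700	U-47,700	substance_class	Other_NP_Synthetic_Opioid
W_18	W-18	substance_class	Other_NP_Synthetic_Opioid
MT_45	MT-45	substance_class	Other_NP_Synthetic_Opioid
AH_7921	AH-7921	substance_class	Other_NP_Synthetic_Opioid
U_48800	U-48,800	substance_class	Other_NP_Synthetic_Opioid
U_49900	U-49,900	substance_class	Other_NP_Synthetic_Opioid
U_4TDP	U-4TDP	substance_class	Other_NP_Synthetic_Opioid
U_50488	U-50,488	substance_class	Other_NP_Synthetic_Opioid
MPF_47700	MPF-47700	substance_class	Other_NP_Synthetic_Opioid
Buprenorphine	buprenorphine	substance_class	Opioid
Heroin	heroin	substance_class	Opioid
Morphine	morphine	substance_class	Opioid
Loperamide	loperamide	substance_class	Opioid
Methadone	methadone	substance_class	Opioid
Hydrocodone	hydrocodone	substance_class	Opioid
Oxycodone	oxycodone	substance_class	Opioid
Hydromorphone	hydromorphone	substance_class	Opioid
Poppy_Tea	Poppy Tea	substance_instance	Morphine
Cannabis	cannabis	substance_class	Cannabinoid
Synthetic_Cannabinoid	synthetic cannabinoid	substance_class	Cannabinoid
Tablet	tablet	form
Powder	powder	form
Transdermal	transdermal	form
Crush	crush	preparation
Eyeball	eyeball	preparation
Finalize_Early	finalize early	preparation
Injection	injection	route
Insufflation	insufflation	route
Dissociative_Disorder	dissociative disorder	dsm5_category
Anxiety_Disorder	anxiety disorder	dsm5_category
Substance_Use_And_Addictive_Disorder	substance use and addictive disorder	dsm5_category
Schizophrenia_Spectrum	schizophrenia spectrum	dsm5_category
Sleep_Wake_Disorder	sleep-wake disorder	dsm5_category
Paraphilic_Disorders	paraphilic disorders	dsm5_category
Gender_Dysphoria	gender dysphoria	dsm5_category
Neurodevelopmental_Disorders	neurodevelopmental disorders	dsm5_category
Sexual_Dysfunctions	sexual dysfunctions	dsm5_category
Personality_Disorders	personality disorders	dsm5_category
Trauma_And_Stressor_Related_Disorder	trauma and stressor related disorder	dsm5_category
Disruptive_Impulse_Control_And_Conduct_Disorder	disruptive, impulse, control, and conduct disorder	dsm5_category
Psychotic_Disorders	psychotic disorders	dsm5_category
Bipolar_And_Related_Disorders	bipolar and related disorders	dsm5_category
Elimination_Disorders	elimination disorders	dsm5_category
Depressive_Disorders	depressive disorders	dsm5_category
Obsessive_Compulsive_Related_Disorder	obsessive-compulsive related disorder	dsm5_category
Feeding_And_Eating_Disorders	feeding and eating disorders	dsm5_category
Neurocognitive_Disorders	neurocognitive disorders	dsm5_category
Suicidal_Behavior_Or_Ideation	suicidal behavior or ideation	dsm5_category
Anxiety	anxiety	mental_health_term	Anxiety_Disorder
Cannabis_Use_Disorder	cannabis use disorder	mental_health_term	Substance_Use_And_Addictive_Disorder
Depression	depression	mental_health_term	Depressive_Disorders
Insomnia	insomnia	mental_health_term	Sleep_Wake_Disorder
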