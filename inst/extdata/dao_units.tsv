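id	canonical_label	dimension	to_grams	surface_forms
Caps	CAPSULE	count		caps|cap|capsule|capsules
Ml	MILLILITER	volume		ml|milliliter|milliliters
Bottle	BOTTLE	count		bottle|bottles
Mg	MILLIGRAM	mass	0.001	mg|milligram|milligrams
Mcg	MICROGRAM	mass	0.000001	mcg|ug|µg|microgram|micrograms
Gram	GRAM	mass	1	g|gram|grams
Ounce	OUNCE	mass	28.3495	oz|ounce|ounces
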