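aa	pathway_id	gene_symbol	ec_number	product
alanine	ala_dehydrogenase	ald	1.4.1.1	pyruvate
alanine	ala_transaminase	alaT	2.6.1.2	pyruvate
arginine	arg_deiminase	arcA	3.5.3.6	ornithine
arginine	arg_deiminase	arcB	2.1.3.3	ornithine
arginine	arg_deiminase	arcC	2.7.2.2	ornithine
asparagine	asn_via_aspartate	ansA	3.5.1.1	fumarate
asparagine	asn_via_aspartate	aspA	4.3.1.1	fumarate
aspartate	asp_ammonia_lyase	aspA	4.3.1.1	fumarate
cysteine	cys_desulfhydrase	dcyD	4.4.1.15	pyruvate
glutamate	glu_dehydrogenase	gdhA	1.4.1.2	2-oxoglutarate
glutamine	gln_gogat	gltB	1.4.1.13	2-oxoglutarate
glutamine	gln_gogat	gltD	1.4.1.13	2-oxoglutarate
glutamine	gln_gogat	gdhA	1.4.1.2	2-oxoglutarate
glycine	gly_decarboxylating	gcvPA	1.4.4.2	pyruvate
glycine	gly_decarboxylating	gcvPB	1.4.4.2	pyruvate
glycine	gly_decarboxylating	gcvH	NA	pyruvate
glycine	gly_decarboxylating	gcvT	2.1.2.10	pyruvate
glycine	gly_decarboxylating	glyA	2.1.2.1	pyruvate
glycine	gly_decarboxylating	sdaA	4.3.1.17	pyruvate
histidine	his_hut	hutH	4.3.1.3	glutamate
histidine	his_hut	hutU	4.2.1.49	glutamate
histidine	his_hut	hutI	3.5.2.7	glutamate
histidine	his_hut	ftcD	2.1.2.5	glutamate
histidine	his_hut	folD	3.5.4.9	glutamate
isoleucine	ile_oxidative	ilvE	2.6.1.42	2-methylbutyryl-CoA
isoleucine	ile_oxidative	vorA	1.2.7.7	2-methylbutyryl-CoA
isoleucine	ile_oxidative	vorB	1.2.7.7	2-methylbutyryl-CoA
isoleucine	ile_oxidative	acdH	1.3.8.5	2-methylbutyryl-CoA
leucine	leu_oxidative	ilvE	2.6.1.42	isovaleryl-CoA
leucine	leu_oxidative	vorA	1.2.7.7	isovaleryl-CoA
leucine	leu_oxidative	vorB	1.2.7.7	isovaleryl-CoA
leucine	leu_oxidative	ivd	1.3.8.4	isovaleryl-CoA
lysine	lys_fermentation	kamA	5.4.3.2	butyrate
lysine	lys_fermentation	kamD	5.4.3.3	butyrate
lysine	lys_fermentation	kamE	5.4.3.3	butyrate
lysine	lys_fermentation	kdd	1.4.1.11	butyrate
lysine	lys_fermentation	kce	2.3.1.247	butyrate
lysine	lys_fermentation	kal	4.3.1.14	butyrate
lysine	lys_fermentation	bcd	1.3.8.1	butyrate
lysine	lys_fermentation	atoD	2.8.3.9	butyrate
methionine	met_gamma_lyase	mdeA	4.4.1.11	propionyl-CoA
methionine	met_gamma_lyase	pflB	2.3.1.54	propionyl-CoA
phenylalanine	phe_oxidative	arAT	2.6.1.57	phenylacetyl-CoA
phenylalanine	phe_oxidative	porA	1.2.7.8	phenylacetyl-CoA
phenylalanine	phe_oxidative	porB	1.2.7.8	phenylacetyl-CoA
proline	pro_oxidative	putB	1.5.5.2	glutamate
proline	pro_oxidative	pruA	1.2.1.88	glutamate
serine	ser_deaminase	sdaA	4.3.1.17	pyruvate
serine	ser_deaminase	sdaB	4.3.1.17	pyruvate
threonine	thr_aldolase	ltaE	4.1.2.48	glycine
threonine	thr_dehydrogenase	tdh	1.1.1.103	glycine
threonine	thr_dehydrogenase	kbl	2.3.1.29	glycine
threonine	thr_ammonia_lyase	tdcB	4.3.1.19	2-oxobutyrate
tryptophan	trp_tryptophanase	tnaA	4.1.99.1	indole + pyruvate
tyrosine	tyr_oxidative	tyrB	2.6.1.57	4-hydroxyphenylacetyl-CoA
tyrosine	tyr_oxidative	porA	1.2.7.8	4-hydroxyphenylacetyl-CoA
tyrosine	tyr_oxidative	porB	1.2.7.8	4-hydroxyphenylacetyl-CoA
valine	val_oxidative	ilvE	2.6.1.42	isobutyryl-CoA
valine	val_oxidative	vorA	1.2.7.7	isobutyryl-CoA
valine	val_oxidative	vorB	1.2.7.7	isobutyryl-CoA
valine	val_oxidative	acdI	1.3.8.5	isobutyryl-CoA
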