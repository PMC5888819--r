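section	label	count	percent	mean	sd
Site	Colon	169	77.9	NA	NA
Site	Rectal	48	22.1	NA	NA
Sex	Male	118	54.4	NA	NA
Sex	Female	99	45.6	NA	NA
Age	Mean (SD)	NA	NA	64.8	10.1
Race	Non-Hispanic white	161	74.2	NA	NA
Race	Hispanic	14	6.5	NA	NA
Race	Non-Hispanic black	8	3.7	NA	NA
Race	Unknown	34	15.7	NA	NA
Tumor phenotype	TP53 mutated	103	47.5	NA	NA
Tumor phenotype	KRAS mutated	69	31.8	NA	NA
Tumor phenotype	BRAF mutated	21	10.1	NA	NA
Tumor phenotype	CIMP high	45	20.7	NA	NA
Tumor phenotype	MSI	29	13.4	NA	NA
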