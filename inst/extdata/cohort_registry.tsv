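accession	role	first_author	description	country	severity_type	timing	n_survived	n_died
E-MEXP-3567	discovery	Irwin	Children with meningococcal sepsis with or without HIV co-infection	Malawi	NA	Admission to ED	6	6
E-MEXP-3850	discovery	Kwan	Children with meningococcal sepsis	UK	PELOD	Admission to hospital; sampled 0-48 h	19	5
E-MTAB-1548	discovery	Almansa	Adult surgical patients with sepsis (EXPRESS study)	Spain	APACHE II	Average post-operation day 4 (hospital acquired)	50	24
GSE10474	discovery	Howrylak	Adults in MICU with sepsis with or without ALI	USA	APACHE II	Admission to ICU	22	11
GSE13015a	discovery	Pankla	Adults with sepsis, many from Burkholderia	Thailand	NA	Within 48 h of diagnosis	35	13
GSE13015b	discovery	Pankla	Adults with sepsis, many from Burkholderia	Thailand	NA	Within 48 h of diagnosis	8	7
GSE27131	discovery	Berdal	Adults with severe H1N1 influenza requiring mechanical ventilation	Norway	SAPS II	Admission to ICU	5	2
GSE32707	discovery	Dolinay	Adults in MICU with sepsis with or without ARDS	USA	APACHE II	Admission to ICU	31	17
GSE40586	discovery	Lill	Infants, children, and adults with bacterial meningitis	Estonia	NA	Within 48 h of hospital admission	19	2
GSE63042	discovery	Langley	Adults with sepsis (CAPSOD study)	USA	APACHE II	Admission to ED	76	28
GSE66099	discovery	Wong	Children in ICU with sepsis or septic shock	USA	PRISM	Admission to ICU	171	28
GSE66890	discovery	Kangelaris	Adults in ICU with sepsis with or without ARDS	USA	APACHE III	Admission to ICU	43	14
GSE21802	validation	Bermejo-Martin	Adults in ICU with severe H1N1 influenza	Spain	SOFA	Within 48 h of admission to ICU	7	4
GSE33341	validation	Ahn	Adults with 2+ SIRS criteria and bacteremia	USA	NA	Within 24 h of admission to hospital	49	2
GSE54514	validation	Parnell	Adults in ICU with sepsis	Australia	APACHE II	Admission to ICU	26	9
GSE63990	validation	Tsalik	Adults with bacterial infection plus 2+ SIRS criteria	USA	NA	Admission to ED	64	6
E-MTAB-4421.51	validation	Davenport	Adults with sepsis (GAinS study)	UK	APACHE II	Day of hospital admission	15	7
Duke-HAI	hai	Tsalik	Adults who developed ventilator-associated pneumonia	USA	NA	Hospital days 1-30	60	10
GlueGrant-Burns	hai	Glue Grant	Adults with severe burns (whole blood)	USA	Denver	Hospital days 1-30	84	8
GlueGrant-Trauma	hai	Glue Grant	Adults with severe traumatic injuries (buffy coat)	USA	MODS	Hospital days 1-30	48	1
UF-P50-12H	hai	Moldawer	Adults with hospital-acquired sepsis	USA	SOFA	Hospital days 1-30	66	5
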