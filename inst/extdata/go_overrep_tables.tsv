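# Published PANTHER GO-Slim biological-process overrepresentation rows per
# constitution type: reference-list count (K), target-list count (k), and the
# printed expected value (2 d.p.). The within-table ratio n_mapped/N is shared
# by all rows of one group's table, so expected values can be cross-checked by
# calibrating the ratio from a single anchor row.
group	term_id	term_name	ref_count	target_count	expected
SE	GO:0009410	Response to xenobiotic stimulus	40	12	0.37
SE	GO:0017144	Drug metabolic process	127	21	1.19
SE	GO:0042493	Response to drug	81	16	0.76
SE	GO:0006721	Terpenoid metabolic process	11	5	0.10
SE	GO:0006720	Isoprenoid metabolic process	14	5	0.13
SE	GO:0016101	Diterpenoid metabolic process	10	4	0.09
SE	GO:0070665	Positive regulation of leukocyte proliferation	3	2	0.03
SE	GO:0006940	Regulation of smooth muscle contraction	3	2	0.03
SE	GO:0032946	Positive regulation of mononuclear cell proliferation	3	2	0.03
SE	GO:0050671	Positive regulation of lymphocyte proliferation	3	2	0.03
SY	GO:0044237	Cellular metabolic process	1744	84	32.73
SY	GO:0017144	Drug metabolic process	127	23	2.38
SY	GO:0006631	Fatty acid metabolic process	138	20	2.59
SY	GO:0042221	Response to chemical	576	39	10.81
SY	GO:0009410	Response to xenobiotic stimulus	40	12	0.75
SY	GO:0051186	Cofactor metabolic process	159	19	2.98
SY	GO:0044255	Cellular lipid metabolic process	294	25	5.52
SY	GO:0005975	Carbohydrate metabolic process	185	20	3.47
SY	GO:0097164	Ammonium ion metabolic process	34	10	0.64
SY	GO:0006807	Nitrogen compound metabolic process	38	10	0.71
TE	GO:0042221	Response to chemical	576	22	4.17
TE	GO:0042632	Cholesterol homeostasis	14	6	0.10
TE	GO:0006629	Lipid metabolic process	120	10	0.87
TE	GO:0055088	Lipid homeostasis	33	6	0.24
TE	GO:0050896	Response to stimulus	1190	26	8.61
TE	GO:0017144	Drug metabolic process	127	9	0.92
TE	GO:0009410	Response to xenobiotic stimulus	40	6	0.29
TE	GO:0008202	Steroid metabolic process	44	6	0.32
TE	GO:0044248	Cellular catabolic process	111	8	0.80
TE	GO:0042493	Response to drug	81	7	0.59
TY	GO:0015698	Inorganic anion transport	44	9	0.19
TY	GO:0006123	Mitochondrial electron transport, cytochrome c to oxygen	185	13	0.79
TY	GO:0006809	Nitric oxide biosynthetic process	54	9	0.23
TY	GO:0050916	Sensory perception of sweet taste	55	9	0.24
TY	GO:0006527	Arginine catabolic process	66	9	0.28
TY	GO:0045776	Negative regulation of blood pressure	10	6	0.04
TY	GO:0051339	Regulation of lyase activity	42	8	0.18
TY	GO:0045937	Positive regulation of phosphate metabolic process	45	8	0.19
TY	GO:0044550	Secondary metabolite biosynthetic process	45	8	0.19
TY	GO:0042773	ATP synthesis coupled electron transport	4072	45	17.45
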