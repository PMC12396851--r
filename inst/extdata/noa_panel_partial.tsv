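symbol	inheritance_mode	chromosome_class	gdr_level	tese_class	poi_linked	notes
ADAD2	AR	autosome	moderate	compatible_positive	false
APEX2	XL	X	limited	unknown	false
AR	XL	X	moderate	compatible_positive	false	dominant-negative and LoF alleles reported; encoded XL
BCORL1	XL	X	moderate	unknown	false
C1orf146	AR	autosome	moderate	negative_only	false
DCAF12L1	XL	X	moderate	compatible_positive	false	recurrent whole-gene deletions reported
DMRT1	AD	autosome	moderate	negative_only	false	haploinsufficiency in the context of male infertility
DNMT1	AD	autosome	limited	unknown	false	dominant in the context of male infertility
FANCA	AR	autosome	strong	negative_only	true
FANCB	XL	X	limited	unknown	false
FATE1	XL	X	moderate	compatible_positive	false
KCTD19	AR	autosome	moderate	negative_only	false
LUZP4	XL	X	moderate	negative_only	false
M1AP	AR	autosome	strong	compatible_positive	false	sperm retrieval in about half of carriers
MCM9	AR	autosome	moderate	negative_only	true
MEI1	AR	autosome	moderate	unknown	true
MEIOB	AR	autosome	moderate	negative_only	true
MLH3	AR	autosome	moderate	negative_only	false
MSH4	AR	autosome	strong	negative_only	true	no sperm retrieved in 10 or more carriers
MSL3	XL	X	limited	unknown	false
NANOS2	AR	autosome	limited	unknown	false
PASD1	XL	X	strong	negative_only	false
POTEJ	AR	autosome	limited	unknown	false
PSMC3IP	AR	autosome	moderate	negative_only	true
RAD21L1	AR	autosome	limited	unknown	false
RBBP7	XL	X	moderate	compatible_positive	false	most frequently affected gene in the cohort
SCML1	XL	X	limited	unknown	false
SHOC1	AR	autosome	moderate	negative_only	false
SOX8	AD	autosome	limited	unknown	false	dominant in the context of male infertility
SPO11	AR	autosome	limited	unknown	false
STAG3	AR	autosome	strong	negative_only	true
SYCE1	AR	autosome	strong	negative_only	true	no sperm retrieved in 10 or more carriers
SYCP3	AD	autosome	moderate	negative_only	false	dominant in the context of male infertility
TERB1	AR	autosome	moderate	negative_only	false
TEX11	XL	X	strong	negative_only	false	no sperm retrieved in 10 or more carriers
TEX14	AR	autosome	strong	negative_only	false
THOC2	XL	X	limited	unknown	false
UBR2	AR	autosome	moderate	compatible_positive	true
USP26	XL	X	limited	unknown	false
ZMYM5	AR	autosome	limited	negative_only	false
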