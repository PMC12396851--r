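gene	carrier_id	source	outcome	profile
TEX11	TEX11_c01	cohort	negative	II
TEX11	TEX11_c02	literature	negative	II
TEX11	TEX11_c03	cohort	negative	II
TEX11	TEX11_c04	literature	negative	II
TEX11	TEX11_c05	cohort	negative	II
TEX11	TEX11_c06	literature	negative	II
TEX11	TEX11_c07	cohort	negative	II
TEX11	TEX11_c08	literature	negative	II
TEX11	TEX11_c09	cohort	negative	II
TEX11	TEX11_c10	literature	negative	II
TEX11	TEX11_c11	cohort	negative	II
TEX11	TEX11_c12	literature	negative	II
TEX11	TEX11_c13	cohort	negative	II
TEX11	TEX11_c14	literature	negative	II
TEX11	TEX11_c15	cohort	negative	II
TEX11	TEX11_c16	literature	negative	II
TEX11	TEX11_c17	cohort	negative	II
SYCE1	SYCE1_c01	cohort	negative	II
SYCE1	SYCE1_c02	literature	negative	II
SYCE1	SYCE1_c03	cohort	negative	II
SYCE1	SYCE1_c04	literature	negative	II
SYCE1	SYCE1_c05	cohort	negative	II
SYCE1	SYCE1_c06	literature	negative	II
SYCE1	SYCE1_c07	cohort	negative	II
SYCE1	SYCE1_c08	literature	negative	II
SYCE1	SYCE1_c09	cohort	negative	II
SYCE1	SYCE1_c10	literature	negative	II
SYCE1	SYCE1_c11	cohort	negative	II
SYCE1	SYCE1_c12	literature	negative	II
SYCE1	SYCE1_c13	cohort	negative	II
SYCE1	SYCE1_c14	literature	negative	II
MSH4	MSH4_c01	cohort	negative	II
MSH4	MSH4_c02	literature	negative	II
MSH4	MSH4_c03	cohort	negative	II
MSH4	MSH4_c04	literature	negative	II
MSH4	MSH4_c05	cohort	negative	II
MSH4	MSH4_c06	literature	negative	II
MSH4	MSH4_c07	cohort	negative	II
MSH4	MSH4_c08	literature	negative	II
MSH4	MSH4_c09	cohort	negative	II
MSH4	MSH4_c10	literature	negative	II
KCTD19	KCTD19_c01	cohort	negative	II
KCTD19	KCTD19_c02	literature	negative	II
KCTD19	KCTD19_c03	cohort	negative	II
KCTD19	KCTD19_c04	literature	negative	II
KCTD19	KCTD19_c05	cohort	negative	II
STAG3	STAG3_c01	cohort	negative	II
STAG3	STAG3_c02	literature	negative	II
STAG3	STAG3_c03	cohort	negative	II
TEX14	TEX14_c01	cohort	negative	II
TEX14	TEX14_c02	literature	negative	II
TEX14	TEX14_c03	cohort	negative	II
FANCA	FANCA_c01	cohort	negative	II
FANCA	FANCA_c02	literature	negative	II
MEIOB	MEIOB_c01	cohort	negative	II
MEIOB	MEIOB_c02	literature	negative	II
DMRT1	DMRT1_c01	cohort	negative	II
DMRT1	DMRT1_c02	literature	negative	II
C1orf146	C1orf146_c01	cohort	negative	II
MLH3	MLH3_c01	cohort	negative	II
SHOC1	SHOC1_c01	cohort	negative	II
TERB1	TERB1_c01	cohort	negative	II
SYCP3	SYCP3_c01	cohort	negative	II
MCM9	MCM9_c01	cohort	negative	II
PASD1	PASD1_c01	cohort	negative	II
ZMYM5	ZMYM5_c01	cohort	negative	II
BCORL1	BCORL1_c01	cohort	negative	II
LUZP4	LUZP4_c01	cohort	negative	II
M1AP	M1AP_c01	cohort	negative	II
M1AP	M1AP_c02	literature	negative	II
M1AP	M1AP_c03	cohort	negative	II
M1AP	M1AP_c04	literature	negative	II
M1AP	M1AP_c05	cohort	negative	II
M1AP	M1AP_c06	literature	negative	II
M1AP	M1AP_c07	cohort	positive	II
M1AP	M1AP_c08	literature	positive	II
M1AP	M1AP_c09	cohort	positive	II
M1AP	M1AP_c10	literature	positive	II
M1AP	M1AP_c11	cohort	positive	II
M1AP	M1AP_c12	literature	positive	II
ADAD2	ADAD2_c01	cohort	negative	II
ADAD2	ADAD2_c02	literature	negative	II
ADAD2	ADAD2_c03	cohort	positive	II
ADAD2	ADAD2_c04	literature	positive	II
AR	AR_c01	cohort	negative	II
AR	AR_c02	literature	negative	II
AR	AR_c03	cohort	negative	II
AR	AR_c04	literature	negative	II
AR	AR_c05	cohort	positive	II
DCAF12L1	DCAF12L1_c01	cohort	negative	II
DCAF12L1	DCAF12L1_c02	literature	negative	II
DCAF12L1	DCAF12L1_c03	cohort	positive	II
DCAF12L1	DCAF12L1_c04	literature	positive	II
RBBP7	RBBP7_c01	cohort	negative	II
RBBP7	RBBP7_c02	literature	negative	II
RBBP7	RBBP7_c03	cohort	positive	II
UBR2	UBR2_c01	cohort	negative	II
UBR2	UBR2_c02	literature	positive	II
FATE1	FATE1_c01	cohort	negative	II
FATE1	FATE1_c02	literature	positive	II
SCML1	SCML1_c01	cohort	negative	II
SCML1	SCML1_c02	literature	positive	II
MEI1	MEI1_c01	cohort	negative	II
MEI1	MEI1_c02	literature	positive	II
RAD21L1	RAD21L1_c01	cohort	positive	II
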