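REACTOME_GLYCOLYSIS	synthetic_standin	ENO1	ENO2	ENO3	PFKFB3	PFKFB4	HK1	HK2	GPI	PFKL	PFKM	ALDOA	ALDOB	ALDOC	TPI1	GAPDH	PGK1	PGAM1	PKM	LDHA	SLC2A1	SLC2A3	PDK1	PDK3	PGM1	ADPGK	GALM	PMM2	FBP1	DLD
REACTOME_CHOLESTEROL_BIOSYNTHESIS	synthetic_standin	HMGCR	HMGCS1	SQLE	NSDHL	LSS	FDFT1	FDPS	GGPS1	IDI1	MVD	MVK	PMVK	CYP51A1	DHCR7	DHCR24	EBP	SC5D	MSMO1	TM7SF2	ACAT2	LBR	STARD4	SREBF2	INSIG1
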