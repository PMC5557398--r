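sample_id	family	fusion_gene	mutations	cna
ALL_176	DUX4_IGH	DUX4-IGH	na	ERG deletion
ALL_218	DUX4_IGH	DUX4-IGH	na	inconclusive
ALL_312	DUX4_IGH	DUX4-IGH	NRAS p.G12D	ERG deletion
ALL_371	DUX4_IGH	DUX4-IGH	NRAS p.G12D	ERG deletion
ALL_390	DUX4_IGH	DUX4-IGH	na	ERG deletion
ALL_392	DUX4_IGH	DUX4-IGH	na	ERG deletion
ALL_501	DUX4_IGH	DUX4-IGH	NRAS p.G12S;KMT2D p.H3883fs	ERG deletion
ALL_546	DUX4_IGH	DUX4-IGH	NRAS p.G12S	ERG deletion
ALL_205	DUX4_IGH	DUX4-chr8q24.21-IGH	NRAS p.G12D	inconclusive
ALL_604	ZNF384_r	TCF3-ZNF384	PTPN11 p.E76Q	chr7q deletion
ALL_622	ZNF384_r	TCF3-ZNF384	PTPN11 p.T73I	chr7q deletion
ALL_8	ZNF384_r	TAF15-ZNF384	NRAS p.Q61H	none
ALL_52	ZNF384_r	EP300-ZNF384	na	none
ALL_613	ZNF384_r	EP300-ZNF384	na	none
ALL_693	ZNF384_r	EP300-ZNF384	na	none
ALL_257	ZNF384_r	ATP5C1-ZNF384	CREBBP p.R1408C	none
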