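ligand	aptamer	pct_open	pct_closed	distance
ADE	GR(C74U)	19.82	43.22	10.08
6AP	GR(C74U)	18.33	48.49	10.00
3AY	GR(C74U)	19.44	49.12	10.25
3TT	GR(C74U)	11.76	56.64	9.89
2DY	GR(C74U)	18.69	46.28	10.38
ADE	AR	19.82	43.22	10.08
6AP	AR	23.83	39.74	10.07
3AY	AR	15.88	52.27	10.14
3TT	AR	13.26	55.36	10.06
2DY	AR	28.23	35.44	10.59
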