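ligand	aptamer	term	mean	se
ADE	GR(C74U)	dEele	-31.48	0.45
ADE	GR(C74U)	dEvdw	-25.45	0.28
ADE	GR(C74U)	dEint	1.42	0.02
ADE	GR(C74U)	dGnonpol	-2.86	0.02
ADE	GR(C74U)	dGpol	35.54	0.72
ADE	GR(C74U)	dGelepol	4.06	0.46
ADE	GR(C74U)	dGvdwnonpol	-28.30	0.28
ADE	GR(C74U)	dH	-22.83	0.62
ADE	GR(C74U)	TdS	-13.31	0.24
ADE	GR(C74U)	dGbind	-9.53	0.73
ADE	GR(C74U)	dGexp	-8.78	NA
ADE	AR	dEele	-31.67	0.61
ADE	AR	dEvdw	-25.98	0.40
ADE	AR	dEint	1.48	0.02
ADE	AR	dGnonpol	-2.84	0.02
ADE	AR	dGpol	33.64	0.91
ADE	AR	dGelepol	1.97	0.43
ADE	AR	dGvdwnonpol	-28.83	0.39
ADE	AR	dH	-25.38	0.57
ADE	AR	TdS	-13.62	0.31
ADE	AR	dGbind	-11.76	0.41
ADE	AR	dGexp	-9.20	NA
6AP	GR(C74U)	dEele	-34.35	0.90
6AP	GR(C74U)	dEvdw	-27.56	0.32
6AP	GR(C74U)	dEint	1.39	0.02
6AP	GR(C74U)	dGnonpol	-3.01	0.02
6AP	GR(C74U)	dGpol	36.35	0.01
6AP	GR(C74U)	dGelepol	2.00	1.15
6AP	GR(C74U)	dGvdwnonpol	-30.57	0.65
6AP	GR(C74U)	dH	-27.18	0.31
6AP	GR(C74U)	TdS	-14.58	0.79
6AP	GR(C74U)	dGbind	-12.60	0.40
6AP	GR(C74U)	dGexp	-10.57	NA
6AP	AR	dEele	-36.87	0.89
6AP	AR	dEvdw	-27.49	0.38
6AP	AR	dEint	1.50	0.02
6AP	AR	dGnonpol	-3.00	0.02
6AP	AR	dGpol	36.45	0.01
6AP	AR	dGelepol	-0.42	0.89
6AP	AR	dGvdwnonpol	-30.48	0.18
6AP	AR	dH	-29.40	0.38
6AP	AR	TdS	-14.03	0.46
6AP	AR	dGbind	-15.37	0.31
6AP	AR	dGexp	-11.53	NA
3AY	GR(C74U)	dEele	-30.77	0.76
3AY	GR(C74U)	dEvdw	-23.55	0.42
3AY	GR(C74U)	dEint	1.39	0.02
3AY	GR(C74U)	dGnonpol	-2.81	0.01
3AY	GR(C74U)	dGpol	34.63	1.41
3AY	GR(C74U)	dGelepol	3.85	1.25
3AY	GR(C74U)	dGvdwnonpol	-26.36	0.42
3AY	GR(C74U)	dH	-21.12	1.42
3AY	GR(C74U)	TdS	-14.69	0.33
3AY	GR(C74U)	dGbind	-6.42	1.55
3AY	GR(C74U)	dGexp	-6.45	NA
3AY	AR	dEele	-29.49	0.55
3AY	AR	dEvdw	-23.21	0.47
3AY	AR	dEint	1.48	0.02
3AY	AR	dGnonpol	-2.81	0.01
3AY	AR	dGpol	32.31	1.17
3AY	AR	dGelepol	2.81	1.17
3AY	AR	dGvdwnonpol	-26.01	0.47
3AY	AR	dH	-21.72	1.18
3AY	AR	TdS	-14.46	0.28
3AY	AR	dGbind	-7.27	0.98
3AY	AR	dGexp	-7.82	NA
3TT	GR(C74U)	dEele	-32.23	1.09
3TT	GR(C74U)	dEvdw	-22.90	0.48
3TT	GR(C74U)	dEint	1.40	0.01
3TT	GR(C74U)	dGnonpol	-2.75	0.02
3TT	GR(C74U)	dGpol	34.88	1.50
3TT	GR(C74U)	dGelepol	2.66	1.60
3TT	GR(C74U)	dGvdwnonpol	-25.64	0.47
3TT	GR(C74U)	dH	-21.59	1.90
3TT	GR(C74U)	TdS	-15.29	0.20
3TT	GR(C74U)	dGbind	-6.30	1.86
3TT	GR(C74U)	dGexp	-6.45	NA
3TT	AR	dEele	-32.10	0.49
3TT	AR	dEvdw	-22.48	0.54
3TT	AR	dEint	1.45	0.02
3TT	AR	dGnonpol	-2.76	0.01
3TT	AR	dGpol	32.89	1.06
3TT	AR	dGelepol	0.80	1.13
3TT	AR	dGvdwnonpol	-25.23	0.54
3TT	AR	dH	-22.98	1.18
3TT	AR	TdS	-15.30	0.22
3TT	AR	dGbind	-7.68	1.10
3TT	AR	dGexp	NA	NA
2DY	GR(C74U)	dEele	-25.57	1.49
2DY	GR(C74U)	dEvdw	-20.93	0.44
2DY	GR(C74U)	dEint	1.37	0.02
2DY	GR(C74U)	dGnonpol	-2.70	0.01
2DY	GR(C74U)	dGpol	29.52	1.55
2DY	GR(C74U)	dGelepol	3.96	1.23
2DY	GR(C74U)	dGvdwnonpol	-23.63	0.43
2DY	GR(C74U)	dH	-18.31	1.06
2DY	GR(C74U)	TdS	-13.72	0.25
2DY	GR(C74U)	dGbind	-4.58	1.21
2DY	GR(C74U)	dGexp	NA	NA
2DY	AR	dEele	-24.71	1.13
2DY	AR	dEvdw	-20.43	0.44
2DY	AR	dEint	1.51	0.02
2DY	AR	dGnonpol	-2.73	0.01
2DY	AR	dGpol	28.74	0.87
2DY	AR	dGelepol	4.03	0.93
2DY	AR	dGvdwnonpol	-23.17	0.43
2DY	AR	dH	-17.63	1.10
2DY	AR	TdS	-13.22	0.22
2DY	AR	dGbind	-4.41	1.14
2DY	AR	dGexp	NA	NA
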