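protein1	protein2	coexpression	experiments	database	textmining	combined_score
SREBF1	SCAP	0.05	0.62	0.80	0.71	0.90
SREBF2	SCAP	0.05	0.60	0.80	0.68	0.90
SREBF1	SREBF2	0.32	0.41	0.30	0.62	0.80
SREBF1	INSIG1	0.12	0.58	0.75	0.66	0.90
SREBF2	INSIG1	0.10	0.52	0.70	0.60	0.85
SREBF1	INSIG2	0.08	0.49	0.65	0.55	0.80
SREBF2	INSIG2	0.08	0.47	0.65	0.52	0.80
SREBF1	FASN	0.61	0.35	0.60	0.72	0.90
SREBF2	FASN	0.45	0.30	0.55	0.65	0.85
SREBF1	SCD5	0.38	0.20	0.40	0.48	0.70
SREBF2	SCD5	0.30	0.18	0.35	0.44	0.65
SREBF1	ACSS2	0.28	0.15	0.30	0.40	0.60
ACSS2	FASN	0.66	0.25	0.40	0.52	0.80
ACSS1	ACSS2	0.52	0.22	0.30	0.45	0.70
ACSS2	ACACA	0.48	0.20	0.30	0.42	0.60
ACSS2	SCD5	0.36	0.12	0.20	0.35	0.55
ACACA	FASN	0.78	0.55	0.70	0.80	0.95
FASN	SCD5	0.46	0.18	0.35	0.50	0.75
PPARG	CD36	0.22	0.55	0.70	0.78	0.90
PPARG	FABP3	0.18	0.42	0.60	0.64	0.80
PPARG	LPL	0.20	0.48	0.65	0.70	0.85
PPARG	ADFP	0.15	0.30	0.40	0.55	0.70
PPARG	GPAM	0.12	0.22	0.30	0.46	0.60
PPARG	SCD5	0.25	0.28	0.40	0.50	0.70
PPARG	XDH	0.08	0.15	0.20	0.40	0.50
PPARG	FASN	0.35	0.38	0.55	0.62	0.80
PPARG	PPARGC1A	0.15	0.70	0.80	0.75	0.90
PPARG	PPARGC1B	0.12	0.62	0.75	0.70	0.85
PPARGC1A	PPARGC1B	0.20	0.25	0.30	0.48	0.60
ADFP	CD36	0.41	0.12	0.10	0.30	0.50
CD36	LPL	0.44	0.20	0.30	0.50	0.70
FABP3	CD36	0.35	0.18	0.25	0.42	0.60
GPAM	FASN	0.40	0.15	0.25	0.38	0.60
GPAM	AGPAT6	0.30	0.35	0.60	0.55	0.80
AGPAT6	DGAT1	0.24	0.28	0.50	0.48	0.70
DGAT1	DGAT2	0.28	0.32	0.55	0.50	0.75
GPAM	LPIN1	0.22	0.26	0.45	0.46	0.70
LPIN1	DGAT2	0.15	0.12	0.25	0.35	0.50
SPTLC1	SPTLC2	0.55	0.72	0.85	0.80	0.95
SPTLC1	SGPL1	0.30	0.18	0.35	0.42	0.60
SPTLC2	SGPL1	0.26	0.16	0.30	0.40	0.55
SGPL1	SPHK2	0.20	0.30	0.50	0.52	0.70
OSBP	OSBPL2	0.18	0.15	0.30	0.44	0.60
OSBP	OSBPL10	0.16	0.14	0.30	0.42	0.60
BDH1	OXCT1	0.34	0.20	0.45	0.55	0.80
LPL	VLDLR	0.19	0.35	0.50	0.58	0.70
ABCA1	ABCG2	0.14	0.18	0.35	0.48	0.60
FADS1	FADS2	0.52	0.40	0.65	0.70	0.90
BTN1A1	XDH	0.10	0.58	0.60	0.72	0.80
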