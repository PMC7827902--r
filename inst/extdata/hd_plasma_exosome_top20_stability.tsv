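gene_id	z_score	cv_percent	rank
miR-21-5p	8.14	3.98	1
miR-92a-3p	6.66	5.01	2
miR-486-5p	6.38	5.78	3
miR-26a-5p	4.32	6.49	4
miR-423-5p	4.31	7.13	5
miR-22-3p	3.78	6.40	6
miR-30d-5p	3.24	7.00	7
let-7f-5p	2.44	9.33	8
let-7a-5p	2.42	8.92	9
miR-151a-3p	2.39	5.80	10
miR-451a-5p	2.07	11.10	11
let-7i-5p	1.98	10.58	12
miR-191-5p	1.86	7.34	13
miR-126-3p	1.68	9.48	14
let-7g-5p	1.67	7.68	15
miR-148a-3p	1.60	11.46	16
miR-101-3p	1.25	8.38	17
miR-10a-5p	0.89	6.93	18
let-7b-5p	0.87	9.28	19
miR-320a-3p	0.82	9.43	20
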