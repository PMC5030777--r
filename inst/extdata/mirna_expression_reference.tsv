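#miRNA	status	WT_RPM	MT_RPM	prob	log2fc_printed	consistent
csi-miR156k	known	16.63	0.01	1.00	-10.70	1
csi-miR159	known	25.11	55.64	0.99	1.15	1
csi-miR166d	known	1.45	3.12	0.87	1.10	0
csi-miR172h-5p	known	2.43	0.01	1.00	-7.92	1
csi-miR394	known	0.35	1.72	0.98	2.31	0
csi-miR399e	known	0.72	2.72	0.99	1.91	0
csi-miR5227	known	0.01	6.27	1.00	9.29	1
csi-miR530b	known	1.63	0.79	0.86	-1.05	0
csi-miR535	known	8.01	17.85	0.96	1.16	1
csi-miRN02	novel	31.04	26.06	0.41	-0.25	1
csi-miRN03	novel	1533	2136	1.00	0.48	1
csi-miRN04	novel	2.89	3.56	0.33	0.30	1
csi-miRN06	novel	71.74	46.56	0.86	-0.62	1
csi-miRN12	novel	0.01	54.57	1.00	12.41	1
csi-miRN13	novel	0.01	40.54	1.00	11.98	0
csi-miRN14	novel	20.01	14.91	0.55	-0.42	1
csi-miRN18	novel	37.36	0.01	1.00	-11.87	1
csi-miRN19	novel	0.99	0.01	NA	-6.63	1
csi-miRN21	novel	3.29	0.01	1.00	-8.36	1
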