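candidate_id	mhc_template	peptide_plddt	inter_pae
c_MEVGWYRSPFS	1muj	94.31	11.01
c_EVGWYRSPFSR	1muj	63.47	11.143
c_VGWYRSPFSRV	6mng	74.15	5.485
c_GWYRSPFSRVV	4p23	86.16	6.289
c_WYRSPFSRVVH	4p23	94.55	2.092
c_YRSPFSRVVHL	6mng	63.16	3.407
c_RSPFSRVVHLY	1muj	95.85	7.659
c_SPFSRVVHLYR	4p23	70.6	8.441
c_PFSRVVHLYRN	1muj	61.67	3.933
c_FSRVVHLYRNG	4p23	93.26	3.916
c_SRVVHLYRNGK	4p23	72.55	8.224
c_TTLSFYRPPFL	6mng	94.86	2.402
c_TLSFYRPPFLR	6mng	73.38	11.094
c_LSFYRPPFLRV	1muj	92.95	9.913
c_SFYRPPFLRVR	1muj	96.53	2.597
c_FYRPPFLRVRR	6mng	95.05	11.917
c_YRPPFLRVRRP	6mng	80.35	6.099
c_RPPFLRVRRPF	6mng	94.68	3.791
c_PPFLRVRRPFY	4p23	94.23	3.132
c_PFLRVRRPFYI	4p23	73.88	5.569
c_FLRVRRPFYII	6mng	81.95	11.193
c_LRVRRPFYIIF	1muj	66.26	11.693
c_EMNDSYRNKKP	4p23	75.98	10.403
c_MNDSYRNKKPR	4p23	97.25	2.911
c_NDSYRNKKPRV	6mng	95.85	11.876
c_DSYRNKKPRVF	6mng	86.32	9.129
c_SYRNKKPRVFS	6mng	94.61	2.799
c_YRNKKPRVFSA	1muj	87.78	3.475
c_RNKKPRVFSAG	1muj	94.64	2.166
c_NKKPRVFSAGE	4p23	74.7	8.41
c_KKPRVFSAGET	1muj	92.49	3.261
c_KPRVFSAGETS	6mng	60.7	10.613
c_PRVFSAGETSI	4p23	92.21	2.93
c_YTFWHYEMNFE	6mng	97.57	3.145
c_TFWHYEMNFER	1muj	93.77	3.324
c_FWHYEMNFERV	4p23	95.12	3.756
c_WHYEMNFERVA	6mng	67.58	11.307
c_HYEMNFERVAY	1muj	93.42	2.758
c_YEMNFERVAYL	4p23	86.03	7.556
c_EMNFERVAYLY	4p23	97.83	3.447
c_MNFERVAYLYT	6mng	77.63	3.212
c_NFERVAYLYTV	6mng	68.89	3.417
c_FERVAYLYTVA	1muj	67.34	3.464
c_ERVAYLYTVAV	1muj	95.8	3.716
c_MTNWEYRLAFC	4p23	97.75	2.373
c_TNWEYRLAFCR	1muj	83.43	5.47
c_NWEYRLAFCRV	6mng	97.32	3.265
c_WEYRLAFCRVK	4p23	96.53	9.772
c_EYRLAFCRVKK	4p23	95.14	3.436
c_YRLAFCRVKKT	6mng	60.95	7.757
c_RLAFCRVKKTE	6mng	94.19	5.774
c_LAFCRVKKTEI	1muj	96.3	3.084
c_AFCRVKKTEIV	1muj	71.12	9.433
c_FCRVKKTEIVC	4p23	62.8	11.295
c_CRVKKTEIVCS	4p23	96.44	2.409
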