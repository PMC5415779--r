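name	start	stop	strand
MT-TF	501	650	+
MT-RNR1	651	1633	+
MT-TV	1634	1666	+
MT-RNR2	1667	3250	+
MT-TL	3251	3300	+
MT-TL1	3301	3350	+
MT-ND1	3351	4250	+
MT-TI	4251	4350	+
MT-TQ	4351	4400	+
MT-TM	4401	4450	+
MT-ND2	4451	5533	+
MT-TW	5534	5566	+
MT-TA	5567	5650	+
MT-TN	5651	5750	+
MT-TC	5751	5850	+
MT-TY	5851	5900	+
MT-CO1	5901	7450	+
MT-TS1	7451	7533	+
MT-TD	7534	7566	+
MT-CO2	7567	8250	+
MT-TK	8251	8350	+
MT-ATP8	8351	8550	+
MT-ATP6	8551	9250	+
MT-CO3	9251	9950	+
MT-TG	9951	10050	+
MT-ND3	10051	10333	+
MT-TR	10334	10366	+
MT-ND4L	10367	10750	+
MT-ND4	10751	12150	+
MT-TH	12151	12200	+
MT-TS2	12201	12250	+
MT-TL2	12251	12350	+
MT-ND5	12351	14150	+
MT-ND6	14151	14650	+
MT-TE	14651	14750	+
MT-CYB	14751	15850	+
MT-TT	15851	15950	+
MT-TP	15951	16100	+
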