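gene	condition	time	mean	sd
AP1	LD	8	119.337	7.93577
AP1	LD	10	98.3555	7.93577
AP1	LD	12	152.504	7.93577
AP1	LD	14	321.42	16.5614
AP1	LD	16	570.613	25.7805
AP1	LD	18	694.865	32.8188
AP1	LD	20	793.577	38.2507
AP1	SD	8	75.1148	5.96645
AP1	SD	10	64.6128	5.96645
AP1	SD	12	60.6033	5.96645
AP1	SD	14	91.3341	5.96645
AP1	SD	16	245.644	11.6929
AP1	SD	18	373.159	20.8156
AP1	SD	20	596.645	28.1571
FD	LD	8	34.4011	1.88282
FD	LD	10	38.1754	1.86488
FD	LD	12	37.6077	1.87988
FD	LD	14	42.6093	1.99594
FD	LD	16	44.5657	2.15043
FD	LD	18	49.3362	2.28911
FD	LD	20	51.1928	2.40055
FD	SD	8	31.0848	1.57285
FD	SD	10	30.7159	1.55079
FD	SD	12	28.8087	1.50435
FD	SD	14	30.5166	1.52138
FD	SD	16	32.378	1.68791
FD	SD	18	34.343	1.91329
FD	SD	20	41.9391	2.11427
FTa1	LD	8	0.0906795	2.76324
FTa1	LD	10	5.27257	2.76324
FTa1	LD	12	49.6031	2.78415
FTa1	LD	14	199.55	10.2159
FTa1	LD	16	276.324	12.7421
FTa1	LD	18	252.238	12.9805
FTa1	LD	20	259.363	12.9985
FTa1	SD	8	0	1.24362
FTa1	SD	10	0.280781	1.24362
FTa1	SD	12	2.93221	1.24362
FTa1	SD	14	23.5518	1.28499
FTa1	SD	16	96.4147	4.71501
FTa1	SD	18	120.456	5.88096
FTa1	SD	20	124.362	5.99099
FTa2	LD	8	0.0931277	1.26144
FTa2	LD	10	3.62058	1.26144
FTa2	LD	12	28.9115	1.39207
FTa2	LD	14	98.2171	5.10793
FTa2	LD	16	123.403	6.37104
FTa2	LD	18	124.416	6.49024
FTa2	LD	20	126.144	6.49927
FTa2	SD	8	0	0.985092
FTa2	SD	10	0.318972	0.985092
FTa2	SD	12	6.36138	0.985092
FTa2	SD	14	51.0073	2.5
FTa2	SD	16	95.7342	4.65431
FTa2	SD	18	95.9403	4.97257
FTa2	SD	20	98.5092	4.99795
FTa3	LD	8	0.0318779	0.0609679
FTa3	LD	10	0.0130778	0.0609679
FTa3	LD	12	0.391667	0.0609679
FTa3	LD	14	2.69723	0.15
FTa3	LD	16	5.43616	0.279258
FTa3	LD	18	6.09679	0.298354
FTa3	LD	20	5.76629	0.299877
FTa3	SD	8	0	0.0406748
FTa3	SD	10	0	0.0406748
FTa3	SD	12	0.07388	0.0406748
FTa3	SD	14	0.881413	0.042833
FTa3	SD	16	2.92379	0.157167
FTa3	SD	18	4.06748	0.196032
FTa3	SD	20	3.78407	0.1997
FTb	LD	8	0	4.24503
FTb	LD	10	7.70435	4.24503
FTb	LD	12	97.4329	4.49747
FTb	LD	14	309.516	16.5025
FTb	LD	16	395.548	20.5834
FTb	LD	18	424.503	20.9685
FTb	LD	20	416.932	20.9977
FTb	SD	8	0.051168	0.577573
FTb	SD	10	0.361657	0.577573
FTb	SD	12	0.679363	0.577573
FTb	SD	14	4.02065	0.577573
FTb	SD	16	29.6103	1.5
FTb	SD	18	51.9109	2.79258
FTb	SD	20	57.7573	2.98354
FTc	LD	8	0	2.35101
FTc	LD	10	2.2533	2.35101
FTc	LD	12	13.2102	2.35101
FTc	LD	14	119.81	5.5
FTc	LD	16	224.113	10.2395
FTc	LD	18	235.101	10.9397
FTc	LD	20	215.725	10.9955
FTc	SD	8	0.0530671	0.891714
FTc	SD	10	0.22599	0.891714
FTc	SD	12	0.666888	0.891714
FTc	SD	14	5.91465	0.891714
FTc	SD	16	45.335	2.25
FTc	SD	18	83.5361	4.18888
FTc	SD	20	89.1714	4.47531
LFY	LD	8	50.4733	2.528
LFY	LD	10	42.8507	2.39867
LFY	LD	12	58.8141	3.05055
LFY	LD	14	115.424	5.69093
LFY	LD	16	155.051	8.07161
LFY	LD	18	192.501	9.84405
LFY	LD	20	239.867	11.2271
LFY	SD	8	34.2342	1.7612
LFY	SD	10	27.4617	1.7612
LFY	SD	12	23.6676	1.7612
LFY	SD	14	40.1468	1.93531
LFY	SD	16	81.0976	4.36252
LFY	SD	18	142.095	6.94262
LFY	SD	20	176.12	8.85885
TFL1a	LD	8	121.481	5.64768
TFL1a	LD	10	128.292	5.93399
TFL1a	LD	12	127.121	6.00956
TFL1a	LD	14	112.547	5.64926
TFL1a	LD	16	91.2089	5.0167
TFL1a	LD	18	83.4449	4.40051
TFL1a	LD	20	79.233	3.90262
TFL1a	SD	8	118.649	6.03076
TFL1a	SD	10	130.085	6.32939
TFL1a	SD	12	126.18	6.52935
TFL1a	SD	14	132.727	6.56598
TFL1a	SD	16	126.173	6.21214
TFL1a	SD	18	117.252	5.53756
TFL1a	SD	20	99.721	4.83641
TFL1c	LD	8	98.9534	5.28539
TFL1c	LD	10	112.026	5.5628
TFL1c	LD	12	112.027	5.61568
TFL1c	LD	14	113.209	5.18069
TFL1c	LD	16	94.5385	4.47802
TFL1c	LD	18	74.5497	3.82529
TFL1c	LD	20	64.5028	3.3153
TFL1c	SD	8	114.646	5.76478
TFL1c	SD	10	126.739	6.05913
TFL1c	SD	12	123.945	6.26722
TFL1c	SD	14	129.064	6.28767
TFL1c	SD	16	112.232	5.84383
TFL1c	SD	18	108.484	5.06279
TFL1c	SD	20	79.5667	4.2932
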