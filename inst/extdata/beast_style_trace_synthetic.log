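#Synthetic trace in the BEAST/Tracer log dialect (for parser testing only)
#model: coalescent-JC69 testbed, 5 taxa
Sample	posterior	likelihood	prior	treeModel.rootHeight	popSize
0	-1789.5212	-1784.0021	-5.5191	0.8123	1.0452
1000	-1786.2041	-1781.7734	-4.4307	0.7561	0.9117
2000	-1787.9932	-1782.5401	-5.4531	0.8342	1.2210
3000	-1785.1107	-1780.9919	-4.1188	0.7220	0.8933
4000	-1786.7755	-1781.8042	-4.9713	0.7808	1.0086
5000	-1788.3310	-1783.1579	-5.1731	0.8015	1.1321
6000	-1785.9621	-1781.2243	-4.7378	0.7444	0.9558
7000	-1787.1189	-1782.0467	-5.0722	0.7903	1.0715
8000	-1786.0456	-1781.5038	-4.5418	0.7317	0.9372
9000	-1787.6604	-1782.7741	-4.8863	0.7991	1.0933
10000	-1785.7343	-1781.0912	-4.6431	0.7536	0.9724
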