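# Published per-category regulation odds for NF-kB/RelA ChIP-seq peaks
# (mean and SD across the two strand estimates); N/A = not estimable.
bin	context	mean_odds	sd_odds
0-2k	upstream	6.73	0.49
2k-25k	upstream	1.73	0.18
25k-1Mb	upstream	1.07	0
>1Mb	upstream	0.32	0.07
-2k-0	intron	4.37	0.21
-2k-0	exon	2.19	0.03
-2k-0	downstream_outside_transcript	2.11	0.52
-25k--2k	intron	1.39	0.04
-25k--2k	exon	0.84	0.11
-25k--2k	downstream_outside_transcript	2.01	0.06
-1Mb--25k	intron	0.85	0.05
-1Mb--25k	exon	N/A	N/A
-1Mb--25k	downstream_outside_transcript	1.21	0
<-1Mb	intron	0.18	0.25
<-1Mb	exon	N/A	N/A
<-1Mb	downstream_outside_transcript	0.34	0.01
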