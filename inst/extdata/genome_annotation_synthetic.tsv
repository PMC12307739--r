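chrom	length	cen_start	cen_end
chr1	2.49e+08	99600000	104600000
chr2	2.43e+08	97200000	102200000
chr3	1.98e+08	79200000	84200000
chr4	1.91e+08	76400000	81400000
chr5	1.81e+08	72400000	77400000
chr6	1.71e+08	68400000	73400000
chr7	1.59e+08	63600000	68600000
chr8	1.46e+08	58400000	63400000
chr9	1.41e+08	56400000	61400000
chr10	1.36e+08	54400000	59400000
chr11	1.35e+08	5.4e+07	5.9e+07
chr12	1.34e+08	53600000	58600000
chr13	1.15e+08	4.6e+07	5.1e+07
chr14	1.07e+08	42800000	47800000
chr15	1.02e+08	40800000	45800000
chr16	9e+07	3.6e+07	4.1e+07
chr17	8.1e+07	32400000	37400000
chr18	7.8e+07	31200000	36200000
chr19	5.9e+07	23600000	28600000
chr20	6.3e+07	25200000	30200000
chr21	4.8e+07	19200000	24200000
chr22	5.1e+07	20400000	25400000
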