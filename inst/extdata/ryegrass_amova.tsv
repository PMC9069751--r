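source	df	ss	vc	ms	pct
Among_varieties	10	0.600671997	0.0056253	0.060067	37.27
Within_varieties	22	0.514943428	0.0094685	0.023407	62.73
Total	32	1.115615425	NA	NA	NA
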