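dataset_a	dataset_b	actual	possible
CRS100	CRS101	2	4
CRS100	CRS102	2	3
CRS100	CRS103	2	4
CRS100	CRS104	2	4
CRS100	CRS105	2	4
CRS101	CRS102	3	3
CRS101	CRS103	3	7
CRS101	CRS104	5	7
CRS101	CRS105	3	6
CRS102	CRS103	3	3
CRS102	CRS104	3	3
CRS102	CRS105	3	3
CRS103	CRS104	5	8
CRS103	CRS105	4	6
CRS104	CRS105	4	6
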