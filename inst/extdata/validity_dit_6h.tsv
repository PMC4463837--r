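subject	M1a	M1b	M2a	M2b
1	39.5	50.5	-13.3	-40.4
2	46.3	74.7	36.9	20.9
3	12.9	49.6	-6.1	-3.3
4	10.6	14.3	10.7	-25.4
5	20.9	8.1	21.7	-0.4
6	11.8	41.5	26.2	44.8
7	37.2	50.4	20.9	-30.2
8	8.3	5.9	34.0	61.4
9	11.3	30.8	30.9	21.4
10	19.2	66.5	-7.0	6.8
11	29.0	54.5	-21.5	-17.9
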