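time	x	y
0	0	0
0.1	2.98	-1.15
0.2	4.98	-4.14
0.3	5.47	-7.51
0.4	4.38	-11.04
0.5	2.27	-15.76
0.6	0.99	-20.21
0.7	0.15	-24.68
0.8	-1.25	-28.93
0.9	-3.11	-33.04
1	-5.04	-36.35
1.1	-7.4	-39.19
1.2	-9.54	-41.06
1.3	-11.51	-41.88
1.4	-13.57	-42.52
1.5	-15.98	-43.51
1.6	-18.27	-45.03
1.7	-20.76	-47.31
1.8	-23.21	-50.1
1.9	-24.95	-52.63
2	-25.16	-55.48
2.1	-24.19	-58.34
2.2	-22.9	-61.08
2.3	-20.99	-64.2
2.4	-18.84	-67.08
2.5	-16.91	-69.21
2.6	-14.22	-71.31
2.7	-11.58	-73.86
2.8	-9.18	-76.99
2.9	-6.12	-80.9
3	-4.33	-85.01
3.1	-1.82	-86.88
3.2	2.74	-86.29
3.3	6.33	-86.45
3.4	9.13	-85.68
3.5	11.4	-82.76
3.6	12.68	-81.02
3.7	14.32	-79.79
3.8	16	-78.6
3.9	18.03	-77.07
4	20.83	-74.78
4.1	23.3	-72.26
4.2	25.91	-69.67
4.3	27.01	-68.1
4.4	28.45	-66.37
4.5	30.34	-64.54
4.6	32.3	-62.27
4.7	33.49	-59.44
4.8	33.68	-56.36
4.9	32.9	-54.26
5	31.33	-53.14
5.1	29.22	-52.72
5.2	26.23	-51.95
5.3	23.34	-50.6
5.4	21.66	-48.82
5.5	20.21	-46.45
5.6	18.74	-43.37
5.7	17.47	-39.87
5.8	16	-36.69
5.9	14.57	-34.22
6	12.63	-32.15
6.1	10.63	-29.67
6.2	9.02	-26.59
6.3	7.25	-23.65
6.4	5.74	-20.25
6.5	5.75	-16.07
6.6	7.55	-13.2
6.7	9.26	-11.68
6.8	10.89	-10.98
6.9	12.78	-10.66
7	14.6	-10.53
7.1	16.71	-10.58
7.2	19.03	-10.56
7.3	20.91	-10.17
7.4	22.32	-8.93
7.5	23.13	-7.64
7.6	23.48	-6.36
7.7	24.08	-4.45
7.8	25.04	-2.38
7.9	26.11	-0.56
8	27.32	1.53
8.1	28.47	3.52
8.2	29.85	5.24
8.3	31.71	6.96
8.4	33.86	8.19
8.5	36.12	8.38
8.6	39.64	7.84
8.7	42.91	6.68
8.8	45.32	4.43
8.9	46.86	1.11
9	47.43	-1.99
9.1	46.49	-5.09
9.2	44.33	-7.34
9.3	41.46	-8.55
9.4	39.05	-8.87
9.5	37.14	-9.37
9.6	35.33	-10.24
9.7	32.99	-10.66
9.8	29.92	-10.97
9.9	27.91	-11.44
10	26.36	-12.1
10.1	24.28	-13.42
10.2	22.29	-15.65
10.3	20.73	-18.98
10.4	21.12	-22.77
10.5	23.33	-26.6
10.6	26.35	-29.89
10.7	29.82	-31.79
10.8	33.08	-33.18
10.9	36.65	-34.23
11	40.01	-35
11.1	43.03	-35.64
11.2	45.73	-36.34
11.3	48.24	-37.26
11.4	50.82	-38.34
11.5	53.75	-39.12
11.6	57.16	-39.02
11.7	60.9	-37.64
11.8	64.66	-35.51
11.9	68.15	-33.55
12	71.62	-32.22
12.1	75.49	-32.15
12.2	79.01	-33.63
12.3	79.17	-36.11
12.4	77.87	-38.58
12.5	76.46	-40.99
12.6	73.79	-42.33
12.7	71.7	-43.94
12.8	70.09	-46.44
12.9	68.75	-49.7
13	68.09	-53.39
13.1	65.79	-55.81
13.2	62.55	-57.25
13.3	59.05	-58.26
13.4	55.3	-58.77
13.5	52.77	-58.41
13.6	50.58	-57.68
13.7	47.8	-56.75
13.8	45	-55.95
13.9	42.95	-55.45
14	41.61	-54.92
14.1	39.96	-54.21
14.2	37.69	-53.42
14.3	35.34	-52.39
14.4	32.37	-51.02
14.5	29.75	-49.92
14.6	26.89	-48.42
14.7	24.45	-46.64
14.8	21.87	-45.24
14.9	18.43	-44.25
15	14.96	-44.16
15.1	11.77	-44.8
15.2	9.04	-45.76
15.3	5.2	-46.62
15.4	1.58	-46.57
15.5	-2.5	-46.57
15.6	-7.56	-46.71
15.7	-13.05	-47.38
15.8	-18.5	-48.75
15.9	-23.64	-50.88
16	-27.68	-53.58
16.1	-30.58	-57.38
16.2	-31.9	-61.47
16.3	-31.5	-65.35
16.4	-29.89	-68.21
16.5	-26.92	-70.08
16.6	-22.86	-70.93
16.7	-18.71	-70.57
16.8	-15.06	-68.95
16.9	-12.25	-66.72
17	-9.83	-64.37
17.1	-6.5	-61.41
17.2	-3.66	-58.24
17.3	-1.71	-53.97
17.4	-1.91	-49.64
17.5	-2.87	-46.26
17.6	-3.63	-43.04
17.7	-4.26	-40.23
17.8	-5.09	-37.8
17.9	-5.59	-34.61
18	-4.3	-31.19
18.1	-1.08	-29.03
18.2	2.74	-28.27
18.3	6.76	-28.12
18.4	11.11	-28.43
18.5	15.4	-28.25
18.6	18.72	-27.11
18.7	21.3	-25.59
18.8	23.85	-23.72
18.9	26.71	-21.45
19	30.36	-20.3
19.1	34	-21.04
19.2	36.91	-23.47
19.3	38.38	-26.85
19.4	39.09	-30.95
19.5	39.83	-34.75
19.6	40.69	-37.38
19.7	42.51	-39.46
19.8	45.54	-40.76
19.9	49.44	-40.61
20	53.23	-39.11
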