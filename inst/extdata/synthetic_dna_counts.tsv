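ref_count	alt_count
50	30
16	14
15	65
15	15
37	13
23	57
47	33
12	18
18	12
17	13
24	26
46	34
18	12
22	28
32	48
51	29
41	39
40	10
19	11
28	22
15	15
13	17
14	16
12	18
11	19
23	7
28	22
35	45
34	16
27	23
47	33
16	14
13	17
27	23
38	12
51	29
53	27
24	26
12	18
11	19
32	48
53	27
21	29
29	21
16	34
28	22
36	44
8	22
42	38
18	32
21	29
19	11
18	12
21	29
39	41
45	35
14	36
18	12
19	31
33	17
21	9
12	18
28	22
44	36
17	13
16	34
21	29
26	24
17	13
23	27
14	16
31	49
19	31
46	34
14	16
33	17
34	46
11	39
12	18
34	16
19	31
19	31
42	38
14	16
47	33
17	33
41	39
11	19
28	52
16	14
19	11
26	24
25	55
40	40
21	9
24	26
18	12
48	32
17	13
18	12
36	14
41	39
19	11
37	43
60	20
33	17
38	42
13	17
6	24
23	27
40	40
26	24
23	27
37	43
56	24
20	30
20	30
13	17
18	12
19	31
54	26
18	12
13	17
15	15
14	16
16	14
21	9
18	12
10	20
16	14
33	47
50	30
26	24
12	18
15	15
20	30
47	33
23	27
29	21
31	19
50	30
32	48
19	11
28	22
19	11
55	25
7	23
18	12
11	19
14	36
28	22
31	19
37	43
14	16
34	46
21	9
21	9
11	19
29	21
18	12
24	26
15	15
33	17
16	14
12	18
15	15
12	18
17	33
17	13
4	26
49	31
41	39
20	10
34	46
18	12
25	25
14	16
22	28
34	46
22	58
19	11
43	37
19	31
28	22
15	15
27	23
30	20
8	22
19	11
10	20
34	46
18	32
14	16
33	47
24	26
16	14
20	30
22	28
18	32
16	14
21	9
38	42
22	8
25	25
18	62
35	45
34	16
20	10
46	34
31	19
32	18
45	35
18	12
8	22
12	18
10	20
54	26
20	30
30	20
18	12
29	21
12	18
38	42
20	30
17	33
44	36
21	9
34	46
53	27
48	32
13	17
15	15
28	52
27	23
27	53
19	11
26	24
29	21
23	27
35	15
20	10
47	33
33	47
16	14
45	35
18	62
30	20
28	52
33	47
33	47
50	30
23	27
33	17
41	39
9	41
35	45
12	18
38	42
11	19
12	18
34	46
37	43
13	17
19	11
27	23
48	32
19	31
16	14
15	15
15	15
24	26
31	49
33	17
18	32
41	39
42	38
9	21
33	47
13	17
9	21
34	46
28	22
11	19
56	24
37	43
15	15
21	9
33	47
29	21
28	22
26	24
10	20
31	19
11	19
9	21
15	15
31	19
33	47
17	33
10	20
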