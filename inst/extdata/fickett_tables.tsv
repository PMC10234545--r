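kind	base	para	prob
position	A	1.9	0.94
position	A	1.8	0.68
position	A	1.7	0.84
position	A	1.6	0.93
position	A	1.5	0.58
position	A	1.4	0.68
position	A	1.3	0.45
position	A	1.2	0.34
position	A	1.1	0.20
position	A	0.0	0.22
position	C	1.9	0.80
position	C	1.8	0.70
position	C	1.7	0.70
position	C	1.6	0.81
position	C	1.5	0.66
position	C	1.4	0.48
position	C	1.3	0.51
position	C	1.2	0.33
position	C	1.1	0.30
position	C	0.0	0.23
position	G	1.9	0.90
position	G	1.8	0.88
position	G	1.7	0.74
position	G	1.6	0.64
position	G	1.5	0.53
position	G	1.4	0.48
position	G	1.3	0.27
position	G	1.2	0.16
position	G	1.1	0.08
position	G	0.0	0.08
position	T	1.9	0.97
position	T	1.8	0.97
position	T	1.7	0.91
position	T	1.6	0.68
position	T	1.5	0.69
position	T	1.4	0.44
position	T	1.3	0.54
position	T	1.2	0.20
position	T	1.1	0.09
position	T	0.0	0.09
content	A	0.33	0.28
content	A	0.31	0.49
content	A	0.29	0.44
content	A	0.27	0.55
content	A	0.25	0.62
content	A	0.23	0.49
content	A	0.21	0.67
content	A	0.19	0.65
content	A	0.17	0.81
content	A	0.00	0.21
content	C	0.33	0.82
content	C	0.31	0.64
content	C	0.29	0.51
content	C	0.27	0.64
content	C	0.25	0.59
content	C	0.23	0.59
content	C	0.21	0.43
content	C	0.19	0.44
content	C	0.17	0.39
content	C	0.00	0.31
content	G	0.33	0.40
content	G	0.31	0.54
content	G	0.29	0.47
content	G	0.27	0.64
content	G	0.25	0.64
content	G	0.23	0.73
content	G	0.21	0.41
content	G	0.19	0.41
content	G	0.17	0.33
content	G	0.00	0.29
content	T	0.33	0.28
content	T	0.31	0.24
content	T	0.29	0.39
content	T	0.27	0.40
content	T	0.25	0.55
content	T	0.23	0.75
content	T	0.21	0.56
content	T	0.19	0.69
content	T	0.17	0.51
content	T	0.00	0.58
weight_position	A	NA	0.26
weight_position	C	NA	0.18
weight_position	G	NA	0.31
weight_position	T	NA	0.33
weight_content	A	NA	0.11
weight_content	C	NA	0.12
weight_content	G	NA	0.15
weight_content	T	NA	0.14
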