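arm	direction	q_value	frequency
3q	gain	0.0001	0.78
8q	gain	0.0001	0.72
20q	gain	0.001	0.63
12p	gain	0.005	0.58
5p	gain	0.01	0.55
1q	gain	0.02	0.48
6p	gain	0.05	0.42
11q	gain	0.1	0.36
4q	loss	0.001	0.72
5q	loss	0.0001	0.68
6q	loss	0.005	0.62
8p	loss	0.0001	0.7
9p	loss	0.002	0.58
9q	loss	0.01	0.55
13q	loss	0.0001	0.71
14q	loss	0.005	0.6
15q	loss	0.001	0.66
16q	loss	0.01	0.61
17p	loss	0.0001	0.74
17q	loss	0.001	0.64
18p	loss	0.005	0.59
18q	loss	0.001	0.67
19p	loss	0.05	0.52
21q	loss	0.02	0.56
22q	loss	0.001	0.69
Xp	loss	0.05	0.53
4p	loss	0.03	0.45
10p	loss	0.08	0.4
11p	loss	0.1	0.34
1p	loss	0.15	0.3
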