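# ca1_synthetic.swc - synthetic CA1-pyramidal-like test fixture (not a reconstruction)
# region_counts list(soma = 1L, axon = 4L, basal = 6L, apical_trunk = 5L, oblique = 6L)
1 1 0 0 0 8 -1
2 2 0 -25 0 0.5 1
3 2 0 -50 0 0.5 2
4 2 0 -75 0 0.5 3
5 2 0 -100 0 0.5 4
6 3 -40 -10 0 0.6 1
7 3 -80 -20 0 0.6 6
8 3 -120 -30 0 0.6 7
9 3 40 -10 0 0.6 1
10 3 80 -20 0 0.6 9
11 3 120 -30 0 0.6 10
12 4 0 50 0 1.1500000000000001 1
13 4 0 100 0 1.0 12
14 4 0 150 0 0.8500000000000001 13
15 4 0 200 0 0.7000000000000001 14
16 4 0 250 0 0.55 15
17 4 30 110 0 0.35 13
18 4 60 120 0 0.35 17
19 4 30 160 0 0.35 14
20 4 60 170 0 0.35 19
21 4 30 210 0 0.35 15
22 4 60 220 0 0.35 21
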