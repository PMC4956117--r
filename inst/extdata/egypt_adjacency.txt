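# Curated first-order adjacency of Egypt's 27 governorates (one undirected
# edge per line, region ids per egypt_governorates.csv).  Hand-curated from
# public administrative geography; Sinai is joined to the mainland through
# the canal-zone governorates so the graph has a single component.
1 8
1 14
1 4
1 7
2 12
2 25
3 5
3 6
3 13
3 26
4 13
4 23
4 27
5 6
6 7
6 9
6 10
7 8
7 13
8 11
8 14
9 10
9 12
10 11
10 12
11 12
11 14
12 14
12 25
13 26
14 15
14 16
14 24
14 25
15 16
15 17
15 23
17 18
17 23
17 24
18 19
18 23
18 24
19 20
19 23
19 24
20 22
20 23
20 24
21 22
21 23
21 24
22 23
22 24
26 27
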