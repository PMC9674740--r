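chromosome,size_mb,gc_percent,gene_density,nor
1,195.47,41.3,2687,FALSE
2,182.11,42.2,3491,FALSE
3,160.04,40.7,2225,FALSE
4,156.51,42.5,2622,FALSE
5,151.84,42.7,2507,FALSE
6,149.74,41.6,2597,FALSE
7,145.44,43.2,3798,FALSE
8,129.4,42.6,2177,FALSE
9,124.6,42.9,2276,FALSE
10,130.7,41.6,2086,FALSE
11,122.08,44,2852,TRUE
12,120.13,42,2002,TRUE
13,120.42,41.9,2127,FALSE
14,124.9,41.4,2111,FALSE
15,104.04,42.2,1620,TRUE
16,98.21,41.2,1367,TRUE
17,94.99,42.9,2005,FALSE
18,90.7,41.7,1218,TRUE
19,61.43,43.1,1283,TRUE
X,171.03,39.2,2291,FALSE
Y,91.74,36.7,423,FALSE
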