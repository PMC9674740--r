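stage,chromosome,signal_kind,n,nvp_pct
spermatogonia-early-preleptotene,1,one-chromosome,38,1.98
spermatogonia-early-preleptotene,2,one-chromosome,26,1.09
spermatogonia-early-preleptotene,3,one-chromosome,28,1.21
spermatogonia-early-preleptotene,4,one-chromosome,38,1.67
spermatogonia-early-preleptotene,5,one-chromosome,40,0.78
spermatogonia-early-preleptotene,6,one-chromosome,28,1.11
spermatogonia-early-preleptotene,7,one-chromosome,40,0.91
spermatogonia-early-preleptotene,8,one-chromosome,24,0.97
spermatogonia-early-preleptotene,9,one-chromosome,28,0.53
spermatogonia-early-preleptotene,10,one-chromosome,28,1.21
spermatogonia-early-preleptotene,11,one-chromosome,10,1.08
spermatogonia-early-preleptotene,12,one-chromosome,22,1.23
spermatogonia-early-preleptotene,13,one-chromosome,18,1.68
spermatogonia-early-preleptotene,14,one-chromosome,32,1.28
spermatogonia-early-preleptotene,15,one-chromosome,24,0.64
spermatogonia-early-preleptotene,16,one-chromosome,22,1.16
spermatogonia-early-preleptotene,17,one-chromosome,18,0.56
spermatogonia-early-preleptotene,18,one-chromosome,22,0.78
spermatogonia-early-preleptotene,19,one-chromosome,4,0.38
spermatogonia-early-preleptotene,X,one-chromosome,10,1.62
spermatogonia-early-preleptotene,Y,one-chromosome,10,1.4
spermatogonia-early-preleptotene,1,two-chromosome,44,1.85
spermatogonia-early-preleptotene,2,two-chromosome,42,2.14
spermatogonia-early-preleptotene,3,two-chromosome,48,2.07
spermatogonia-early-preleptotene,4,two-chromosome,45,1.96
spermatogonia-early-preleptotene,5,two-chromosome,36,2.23
spermatogonia-early-preleptotene,6,two-chromosome,35,1.84
spermatogonia-early-preleptotene,7,two-chromosome,45,2.04
spermatogonia-early-preleptotene,8,two-chromosome,35,1.87
spermatogonia-early-preleptotene,9,two-chromosome,31,1.21
spermatogonia-early-preleptotene,10,two-chromosome,36,1.82
spermatogonia-early-preleptotene,11,two-chromosome,30,1.62
spermatogonia-early-preleptotene,12,two-chromosome,30,2.63
spermatogonia-early-preleptotene,13,two-chromosome,32,2.14
spermatogonia-early-preleptotene,14,two-chromosome,47,1.83
spermatogonia-early-preleptotene,15,two-chromosome,30,1.18
spermatogonia-early-preleptotene,16,two-chromosome,42,1.48
spermatogonia-early-preleptotene,17,two-chromosome,26,1.31
spermatogonia-early-preleptotene,18,two-chromosome,18,1.21
spermatogonia-early-preleptotene,19,two-chromosome,24,0.84
spermatogonia-early-preleptotene,X,two-chromosome,25,1.72
spermatogonia-early-preleptotene,Y,two-chromosome,25,2.6
mid-preleptotene-zygotene,1,one-chromosome,28,1.94
mid-preleptotene-zygotene,2,one-chromosome,10,1.24
mid-preleptotene-zygotene,3,one-chromosome,22,1.22
mid-preleptotene-zygotene,4,one-chromosome,24,1.22
mid-preleptotene-zygotene,5,one-chromosome,8,0.94
mid-preleptotene-zygotene,6,one-chromosome,14,1.76
mid-preleptotene-zygotene,7,one-chromosome,22,1.76
mid-preleptotene-zygotene,8,one-chromosome,16,0.78
mid-preleptotene-zygotene,9,one-chromosome,16,0.86
mid-preleptotene-zygotene,10,one-chromosome,22,1.7
mid-preleptotene-zygotene,11,one-chromosome,8,1.22
mid-preleptotene-zygotene,12,one-chromosome,8,1.58
mid-preleptotene-zygotene,13,one-chromosome,24,0.65
mid-preleptotene-zygotene,14,one-chromosome,14,1.08
mid-preleptotene-zygotene,15,one-chromosome,8,0.99
mid-preleptotene-zygotene,16,one-chromosome,20,1.59
mid-preleptotene-zygotene,17,one-chromosome,8,1
mid-preleptotene-zygotene,18,one-chromosome,20,1.18
mid-preleptotene-zygotene,19,one-chromosome,2,1.46
mid-preleptotene-zygotene,X,one-chromosome,4,1.05
mid-preleptotene-zygotene,Y,one-chromosome,4,2.02
mid-preleptotene-zygotene,1,two-chromosome,43,2.44
mid-preleptotene-zygotene,2,two-chromosome,34,3.59
mid-preleptotene-zygotene,3,two-chromosome,39,3.66
mid-preleptotene-zygotene,4,two-chromosome,47,3
mid-preleptotene-zygotene,5,two-chromosome,37,2.47
mid-preleptotene-zygotene,6,two-chromosome,41,2.76
mid-preleptotene-zygotene,7,two-chromosome,38,2.74
mid-preleptotene-zygotene,8,two-chromosome,36,1.97
mid-preleptotene-zygotene,9,two-chromosome,41,1.91
mid-preleptotene-zygotene,10,two-chromosome,42,2.91
mid-preleptotene-zygotene,11,two-chromosome,47,1.87
mid-preleptotene-zygotene,12,two-chromosome,47,3.02
mid-preleptotene-zygotene,13,two-chromosome,39,2.44
mid-preleptotene-zygotene,14,two-chromosome,52,2.29
mid-preleptotene-zygotene,15,two-chromosome,29,1.36
mid-preleptotene-zygotene,16,two-chromosome,37,2.07
mid-preleptotene-zygotene,17,two-chromosome,32,1.53
mid-preleptotene-zygotene,18,two-chromosome,40,1.68
mid-preleptotene-zygotene,19,two-chromosome,44,1.38
mid-preleptotene-zygotene,X,two-chromosome,44,2.84
mid-preleptotene-zygotene,Y,two-chromosome,44,1.86
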