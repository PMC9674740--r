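stage,chromosome,n_two_signal,n_one_signal,total,single_copy
spermatogonia-early-preleptotene,1,19,44,63,FALSE
spermatogonia-early-preleptotene,2,13,42,55,FALSE
spermatogonia-early-preleptotene,3,14,48,62,FALSE
spermatogonia-early-preleptotene,4,19,45,64,FALSE
spermatogonia-early-preleptotene,5,20,36,56,FALSE
spermatogonia-early-preleptotene,6,14,35,49,FALSE
spermatogonia-early-preleptotene,7,20,45,65,FALSE
spermatogonia-early-preleptotene,8,12,35,47,FALSE
spermatogonia-early-preleptotene,9,14,31,45,FALSE
spermatogonia-early-preleptotene,10,14,36,50,FALSE
spermatogonia-early-preleptotene,11,5,30,35,FALSE
spermatogonia-early-preleptotene,12,11,30,41,FALSE
spermatogonia-early-preleptotene,13,9,32,41,FALSE
spermatogonia-early-preleptotene,14,16,47,63,FALSE
spermatogonia-early-preleptotene,15,12,30,42,FALSE
spermatogonia-early-preleptotene,16,11,42,53,FALSE
spermatogonia-early-preleptotene,17,9,26,35,FALSE
spermatogonia-early-preleptotene,18,11,18,29,FALSE
spermatogonia-early-preleptotene,19,2,24,26,FALSE
spermatogonia-early-preleptotene,X,10,25,35,FALSE
spermatogonia-early-preleptotene,Y,10,25,35,TRUE
mid-preleptotene-zygotene,1,14,43,57,FALSE
mid-preleptotene-zygotene,2,5,34,39,FALSE
mid-preleptotene-zygotene,3,11,39,50,FALSE
mid-preleptotene-zygotene,4,12,47,59,FALSE
mid-preleptotene-zygotene,5,4,37,41,FALSE
mid-preleptotene-zygotene,6,7,41,48,FALSE
mid-preleptotene-zygotene,7,11,38,49,FALSE
mid-preleptotene-zygotene,8,8,36,44,FALSE
mid-preleptotene-zygotene,9,8,41,49,FALSE
mid-preleptotene-zygotene,10,11,42,53,FALSE
mid-preleptotene-zygotene,11,4,47,51,FALSE
mid-preleptotene-zygotene,12,4,47,51,FALSE
mid-preleptotene-zygotene,13,12,39,51,FALSE
mid-preleptotene-zygotene,14,7,52,59,FALSE
mid-preleptotene-zygotene,15,4,29,33,FALSE
mid-preleptotene-zygotene,16,10,37,47,FALSE
mid-preleptotene-zygotene,17,4,32,36,FALSE
mid-preleptotene-zygotene,18,10,40,50,FALSE
mid-preleptotene-zygotene,19,1,44,45,FALSE
mid-preleptotene-zygotene,X,4,44,48,FALSE
mid-preleptotene-zygotene,Y,4,44,48,TRUE
pachytene,1,0,52,52,FALSE
pachytene,2,0,52,52,FALSE
pachytene,3,0,59,59,FALSE
pachytene,4,0,55,55,FALSE
pachytene,5,0,51,51,FALSE
pachytene,6,0,50,50,FALSE
pachytene,7,0,60,60,FALSE
pachytene,8,0,48,48,FALSE
pachytene,9,0,58,58,FALSE
pachytene,10,0,62,62,FALSE
pachytene,11,0,57,57,FALSE
pachytene,12,0,59,59,FALSE
pachytene,13,0,43,43,FALSE
pachytene,14,0,54,54,FALSE
pachytene,15,0,40,40,FALSE
pachytene,16,0,59,59,FALSE
pachytene,17,0,40,40,FALSE
pachytene,18,0,56,56,FALSE
pachytene,19,0,49,49,FALSE
pachytene,X,0,42,42,FALSE
pachytene,Y,0,42,42,TRUE
round-spermatid,1,0,113,113,FALSE
round-spermatid,2,0,108,108,FALSE
round-spermatid,3,0,100,100,FALSE
round-spermatid,4,0,121,121,FALSE
round-spermatid,5,0,109,109,FALSE
round-spermatid,6,0,130,130,FALSE
round-spermatid,7,0,100,100,FALSE
round-spermatid,8,0,126,126,FALSE
round-spermatid,9,0,123,123,FALSE
round-spermatid,10,0,123,123,FALSE
round-spermatid,11,0,113,113,FALSE
round-spermatid,12,0,118,118,FALSE
round-spermatid,13,0,104,104,FALSE
round-spermatid,14,0,122,122,FALSE
round-spermatid,15,0,77,77,FALSE
round-spermatid,16,0,85,85,FALSE
round-spermatid,17,0,103,103,FALSE
round-spermatid,18,0,97,97,FALSE
round-spermatid,19,0,76,76,FALSE
round-spermatid,X,0,52,52,FALSE
round-spermatid,Y,0,52,52,TRUE
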