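"subject_id","condition","pct_nonperm","retention"
"BM1","BM",56.9,41.2
"BM2","BM",51.3,45.6
"BM3","BM",66.2,28.1
"BM4","BM",51.3,44.6
"BM5","BM",44.8,50.5
"UCMD6","UCMD",NA,70.7
"UCMD7","UCMD",NA,60
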