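name,n_subtasks,prerequisites,load_class,mem_class,blast_separable,prereq_only
THREADER,4,PSIPRED;BLAST,Highest,Low,TRUE,FALSE
SAM-T2K,9,BLAST,High,High,TRUE,FALSE
HHpred,7,BLAST,High,Medium,FALSE,FALSE
CS/CSI-BLAST,4,,Low,Low,TRUE,FALSE
COMPASS,7,BLAST,High,High,TRUE,FALSE
pfTools,4,,Medium,Low,TRUE,FALSE
pGenTHREADER,4,BLAST,High,Low,FALSE,FALSE
HMMER,4,,Low,Low,TRUE,FALSE
SPARKS,4,BLAST,High,Medium,FALSE,FALSE
SP3,4,BLAST,High,Medium,FALSE,FALSE
BLAST,1,,Medium,Medium,TRUE,TRUE
PSIPRED,1,,Low,Low,TRUE,TRUE
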