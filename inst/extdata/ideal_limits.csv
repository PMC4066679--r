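tool,instance,pipeline_min,ideal_limit_min
SAM-T2K,m1.small,1271.0,1055.7
SAM-T2K,c1.xlarge,224.5,65.6
SAM-T2K,hi1.4xlarge,168.3,35.7
SP3,m1.small,1312.2,1124.4
SP3,c1.xlarge,118.6,68.1
SP3,hi1.4xlarge,105.7,33.0
CS/CSI-BLAST,m1.small,25.2,15.4
CS/CSI-BLAST,c1.xlarge,6.0,1.23
CS/CSI-BLAST,hi1.4xlarge,4.4,0.47
HMMER,m1.small,29.0,16.0
HMMER,c1.xlarge,6.1,1.0
HMMER,hi1.4xlarge,5.8,0.6
pfTools,m1.small,244.8,226.0
pfTools,c1.xlarge,18.3,12.8
pfTools,hi1.4xlarge,15.5,9.2
THREADER,m1.small,27842.2,23744.0
THREADER,c1.xlarge,2019.3,1488.0
THREADER,hi1.4xlarge,1552.2,1090.4
SPARKS,m1.small,1021.8,1037.7
SPARKS,c1.xlarge,80.0,54.3
SPARKS,hi1.4xlarge,73.3,41.8
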