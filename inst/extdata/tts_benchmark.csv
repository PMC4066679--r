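tool,instance,tts_min,cts_usd
HMMER,t1.micro,33.1,0.01
HMMER,m1.small,29.0,0.03
HMMER,m1.medium,19.6,0.04
HMMER,m1.large,9.8,0.04
HMMER,c1.medium,10.6,0.03
HMMER,c1.xlarge,6.1,0.06
HMMER,hi1.4xlarge,5.8,0.30
SP3,t1.micro,NA,NA
SP3,m1.small,1312.3,1.31
SP3,m1.medium,670.7,1.34
SP3,m1.large,458.0,1.83
SP3,c1.medium,356.7,0.86
SP3,c1.xlarge,118.6,1.15
SP3,hi1.4xlarge,105.7,5.46
THREADER,t1.micro,96905.8,32.30
THREADER,m1.small,27842.2,27.84
THREADER,m1.medium,11551.2,23.10
THREADER,m1.large,2897.2,11.59
THREADER,c1.medium,6833.8,16.52
THREADER,c1.xlarge,2019.3,19.52
THREADER,hi1.4xlarge,1552.2,80.20
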