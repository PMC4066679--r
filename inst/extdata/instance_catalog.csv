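name,category,cores,mem_gb,relative_cost,launch_mean_min,launch_sd_min,nonsupport_tools
t1.micro,E,1,0.613,1,1.99,0.2,HHpred;COMPASS;SAM-T2K;pGenTHREADER;SPARKS;SP3
m1.small,G,1,1.7,3,1.86,0.08,COMPASS;SAM-T2K;pGenTHREADER
m1.medium,G,1,3.7,6,1.80,0.15,SAM-T2K
m1.large,M,2,7.5,12,1.70,0.08,
c1.medium,C,2,1.7,7.25,1.68,0.17,COMPASS;SAM-T2K;pGenTHREADER
c1.xlarge,C,8,7,29,1.69,0.08,
hi1.4xlarge,S,16,60.5,155,2.01,0.16,
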