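tool,instance,subtask,n_sequences,minutes
pfTools,t1.micro,chain_main,20,316.5
pfTools,t1.micro,domain_main,20,331.6
pfTools,t1.micro,chain_post,20,33.4
pfTools,t1.micro,domain_post,20,21.5
pfTools,m1.small,chain_main,20,137.1
pfTools,m1.small,domain_main,20,90.1
pfTools,m1.small,chain_post,20,9.7
pfTools,m1.small,domain_post,20,7.9
pfTools,m1.medium,chain_main,20,62.2
pfTools,m1.medium,domain_main,20,42.9
pfTools,m1.medium,chain_post,20,6.1
pfTools,m1.medium,domain_post,20,4.4
pfTools,m1.large,chain_main,20,31.1
pfTools,m1.large,domain_main,20,21.5
pfTools,m1.large,chain_post,20,3.4
pfTools,m1.large,domain_post,20,2.7
pfTools,c1.medium,chain_main,20,32.8
pfTools,c1.medium,domain_main,20,22.5
pfTools,c1.medium,chain_post,20,3.9
pfTools,c1.medium,domain_post,20,3.1
pfTools,c1.xlarge,chain_main,20,9.5
pfTools,c1.xlarge,domain_main,20,6.5
pfTools,c1.xlarge,chain_post,20,1.1
pfTools,c1.xlarge,domain_post,20,1.2
pfTools,hi1.4xlarge,chain_main,20,7.7
pfTools,hi1.4xlarge,domain_main,20,5.3
pfTools,hi1.4xlarge,chain_post,20,1.3
pfTools,hi1.4xlarge,domain_post,20,1.2
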