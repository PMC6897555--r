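group,component,mean_change,t,df,p,reported_d
Learner,N1,0.625,3.406,24,0.002,0.683
NonLearner,N1,0.1516,0.514,8,0.621,0.171
Learner,LPC,0.5325,3.560,24,0.002,0.712
NonLearner,LPC,0.0205,0.514,8,0.861,0.060
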