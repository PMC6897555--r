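group,measure,mean,t,df,p,reported_d
Learner,diffB,1.801,6.453,17,0.01,1.521
Learner,diffW,-0.43,-1.386,17,0.184,0.331
NonLearner,diffB,0.776,1.935,14,0.073,0.504
NonLearner,diffW,0.376,1.609,14,0.130,0.244
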