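level,covariant_features,learners,borderlines,nonlearners,trials_to_learn_mean,trials_to_learn_se,accuracy_mean,accuracy_se
1,6/6,7,1,3,140,20,79,4.1
2,5/6,8,0,3,194,41,71,4.7
3,4/6,5,3,2,278,61,65,3.04
4,3/6,8,0,2,138,20,82,3.7
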