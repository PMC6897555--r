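level,covariant_features,immediate_learners,successful_learners,borderlines,nonlearners,trials_to_learn_mean,trials_to_learn_se,accuracy_mean,accuracy_se
easier,5/6,6,10,0,5,106,33,62,3.17
harder,4/6,0,8,2,10,262,32,81,3.09
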