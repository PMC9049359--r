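study,itr_fixed,itr_dynamic
response_threshold,37.71,41.08
margin_threshold,NA,57.3
softmax_cost,134.25,164.72
bayes_threshold,239.6,257.6
target_specific_bayes,300.7,330.4
this_study,63.44,81.14
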