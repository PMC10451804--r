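experiment,loss,sensitivity,specificity,balanced_accuracy
two_class,cross_entropy,0.724,0.809,0.767
two_class,focal,0.730,0.816,0.773
two_class_disregard_equivocal,cross_entropy,0.714,0.923,0.819
two_class_disregard_equivocal,focal,0.772,0.868,0.820
three_class,focal,0.740,0.712,0.726
three_class,cross_entropy,0.707,0.851,0.776
three_class,uncertainty_ce,0.761,0.842,0.802
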