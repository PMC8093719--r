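quantity,value
sampled_individuals,933
inferred_females,310
inferred_males,319
largest_component,1487
n_other_components,5
other_components_total,75
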