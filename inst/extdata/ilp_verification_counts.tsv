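in_silico	genotype	n
empty	hom_empty	541
occupied	hom_occupied	128
occupied	het_empty_occupied	94
empty	hom_variant_other_size	30
empty	het_empty_variant	13
occupied	het_occupied_variant	1
empty	het_empty_occupied	11
empty	hom_occupied	8
occupied	hom_empty	1
empty	no_amplification	13
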