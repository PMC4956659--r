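# Toy design targets: id <TAB> dot-bracket [<TAB> template]
# HH_synthetic: 85-nt cis-acting Hammerhead ribozyme with its conserved-motif
# template; the base-pair layout is a synthetic reconstruction.
hairpin9	(((...)))
htype14	((..[[..))..]]
pk22	((((....[[[.))))...]]]
HH_synthetic	..[[[[[....(((((.........(((..]]]]]...........)))..(((((((...)))))))...))))).........	ooooooooooooooooCCUGAUGAGoooooooooooooooGCGAAAooooooooooooooooooooooUCGoooooooooooooo
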