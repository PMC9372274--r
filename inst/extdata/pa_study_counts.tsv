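quantity	value
n_analysis	648
n_cluster1	522
n_cluster2	94
n_cluster3	32
n_enrolled	715
n_reached_followup	366
n_female	295
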