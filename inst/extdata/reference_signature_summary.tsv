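statistic	value
total_reads	480343
mapped_sequences	59284
unique_signatures	12028
singleton_signatures	4681
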