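library	n_sequences	n_loci
drought_1_5h	17758	4574
drought_6_10h	10367	3138
cold_1_5h	2104	1595
cold_6_10h	2869	2018
salt_1_5h	10247	3645
salt_6_10h	6148	2417
no_treatment	9791	4162
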