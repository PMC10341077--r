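sample	chromosome	start	end	total_cn	minor_cn
#purity=0.62
#ploidy=2.1
EX01	chrA	1	15000000	2	0
EX01	chrA	15000001	100000000	2	1
EX01	chrB	1	60000000	2	1
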