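chromosome	length	centromere_start	centromere_end	p_telomere_assembled	q_telomere_assembled
chrA	100000000	40000001	41000000	true	true
chrB	60000000	30000001	31000000	true	true
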