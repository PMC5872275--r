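name	fwd	rev	enzyme	size_min	size_max	max_mismatch
AmEu1	AmEu1-f	AmEu1-r	AluI	120	160	3
AmEu2	AmEu2-f	AmEu2-r	HinfI	120	160	3
AmCarp	AmCarp-f	AmCarp-r	HspAI	120	160	3
AmCar	AmCar-f	AmCar-r	MspI	120	160	3
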