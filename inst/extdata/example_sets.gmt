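over_dominant_set	synthetic
background_set	synthetic	g00001	g00002	g00003	g00004	g00005	g00006	g00007	g00008	g00009	g00010
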