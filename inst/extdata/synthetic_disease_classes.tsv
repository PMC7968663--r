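term	node_id
psychiatric	histamine receptor h1
psychiatric	dopamine receptor d2
psychiatric	serotonin receptor 2a
metal_handling	superoxide dismutase
metal_handling	ceruloplasmin
metal_handling	copper ion
infection	penicillin-binding protein 2
infection	thymidine kinase
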