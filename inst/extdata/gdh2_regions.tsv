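residue_start	residue_end	region
54	69	N-terminal helix (mature protein start)
70	80	N-terminal helix, allosteric surface
140	170	active-site entrance
330	430	NAD domain
440	515	antenna
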