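substitution	transition_type	potential_cause	consequence
c.94C>A	none	mutation	synonymous
c.103G>A	TS2	DNA degradation	G35R
c.123G>T	none	mutation	synonymous
c.232G>A	TS2	DNA degradation	A78T
c.460A>C	none	mutation	T154P
c.582C>T	TS2	DNA degradation	synonymous
c.986C>T	TS2	DNA degradation	A329V
c.1072A>C	none	mutation	I358L
c.1184G>A	TS2	DNA degradation	R395K
c.1241A>G	TS1	DNA degradation	D414G
c.1371A>G	TS1	DNA degradation	synonymous
c.1395C>T	TS2	DNA degradation	synonymous
c.1492T>G	none	mutation	S498A
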