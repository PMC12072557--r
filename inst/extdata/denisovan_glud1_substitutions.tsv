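substitution	transition_type	potential_cause	consequence
c.342T>C	TS1	DNA degradation	NA
c.376G>A	TS2	DNA degradation	NA
c.462T>C	TS1	DNA degradation	NA
c.527T>C	TS1	DNA degradation	NA
c.771T>C	TS1	DNA degradation	NA
c.909A>C	none	synonymous mutation	NA
c.942A>G	TS1	DNA degradation	NA
c.1175A>G	TS1	DNA degradation	NA
c.1255G>A	TS2	DNA degradation	NA
c.1479G>A	TS2	DNA degradation	NA
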