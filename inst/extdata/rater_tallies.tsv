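rater	equivalent_to	broader_than	narrower_than
A	50	106	11
B	55	226	26
C	36	84	37
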