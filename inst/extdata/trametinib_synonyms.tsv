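TRAMETINIB	trametinib
TRAMETINIB DIMETHYL SULFOXIDE	trametinib
DABRAFENIB\TRAMETINIB	trametinib
MEKINIST	trametinib
GSK1120212	trametinib
TAFINLAR COMBO	trametinib
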