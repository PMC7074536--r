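name,formula,residue_mass
pentose,C5H8O4,132.0422588
hexose,C6H10O5,162.0528234
HexNAc,C8H13NO5,203.0793725
deoxyhexose,C6H10O4,146.0579088
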