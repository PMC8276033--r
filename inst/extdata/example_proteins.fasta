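>P1 ER-resident example, tail TAEKDEL
MAAAAAAAGGGGGTAEKDEL
>P2 second protein sharing the TAEKDEL tail, sequence wrapped
MSSSSSSSPP
PPPTAEKDEL
>P3 too short to yield a seven-residue tail
MKDEL
>P4 ambiguous residue inside the extracted tail
MCCCCCCCCCCCCTAEKDXL
>P5 divergent tail LIGSLEL with trailing stop symbol
MLLLLLLLVVVVVLIGSLEL*
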