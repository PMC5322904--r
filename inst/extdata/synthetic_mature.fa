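>syn-miR01a synthetic example mature, locus a
UGGACUGUUGUCUGGCAUCGA
>syn-miR01b synthetic example mature, locus b (same mature as 01a)
UGGACUGUUGUCUGGCAUCGA
>syn-miR02a synthetic example mature
ACCGUAGGCUUACGGAUCAGU
>syn-miR03a synthetic example mature
GUUCACCAAGGCUAAUCGGUA
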