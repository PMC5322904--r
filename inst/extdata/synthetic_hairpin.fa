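>syn-miR01a synthetic example hairpin, locus a
CAGUUGGACUGUUGUCUGGCAUCGAGGAUACCGAUGCCAGACAACAGUCCUU
>syn-miR01b synthetic example hairpin, locus b
AAUGGACUGUUGUCUGGCAUCGAGCCUUCGAUGCCAGACAACAGUCCAAGGC
>syn-miR02a synthetic example hairpin
GGACCGUAGGCUUACGGAUCAGUGAUCACUGAUCCGUAAGCCUACGGUCCAA
>syn-miR03a synthetic example hairpin
UUGUUCACCAAGGCUAAUCGGUAGCAAUACCGAUUAGCCUUGGUGAACAAGG
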