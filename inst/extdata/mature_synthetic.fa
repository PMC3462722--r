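>osa-miR168a monocot miR168 variant
UCGCUUGGUGCAGAUCGGGAC
>zma-miR168a monocot miR168 variant
UCGCUUGGUGCAGAUCGGGAC
>zma-miR168b monocot miR168 variant
UCGCUUGGUGCAGAUCGGGAC
>sbi-miR168 monocot miR168 variant
UCGCUUGGUGCAGAUCGGGAC
>ath-miR168a dicot miR168 variant
UCGCUUGGUGCAGGUCGGGAA
>ath-miR168b dicot miR168 variant
UCGCUUGGUGCAGGUCGGGAA
>gma-miR168 dicot miR168 variant
UCGCUUGGUGCAGGUCGGGAA
>bna-miR168 dicot miR168 variant
UCGCUUGGUGCAGGUCGGGAA
>osa-miR535 synthetic stand-in sequence
UACGACCAUGUCUCGCCAUCA
>ath-miR535 synthetic stand-in sequence
UCCUGGACACCGGCUUUGGGG
>osa-miR156a synthetic stand-in sequence
AGGACGCGAGCUCUAACUGCA
>ath-miR156a synthetic stand-in sequence
UGGCGCUUGUGAGUCCCCCCG
>osa-miR159a synthetic stand-in sequence
UAGGUGCGAUAAAUACUGGCU
>ath-miR159a synthetic stand-in sequence
GGUCUGACGCCUUUCGAGCAU
>osa-miR396a synthetic stand-in sequence
AGUUAGUCCUGAUACCUAUUC
>ath-miR396a synthetic stand-in sequence
GCGCGACUAAUUCAACGGUGC
>gma-miR1507a synthetic stand-in sequence
UAGGGUACGUGCGGUUGUCGG
>gma-miR1507b synthetic stand-in sequence
UAACCUAGGCUUAAAGACUUC
>gma-miR3522 synthetic stand-in sequence
AUAAGAGCAUUUUCCGCACGA
>lsa-miR9501 synthetic stand-in sequence
ACAUCGGGAUGUAGGGAGCAC
>hsa-miR-21 synthetic stand-in sequence
UCUAUCGGUCUUAUCGGGUGG
>mmu-miR-122 synthetic stand-in sequence
AGCUUACAUGUGUCAACUCAA
>bmo-miR-279 synthetic stand-in sequence
AAAUCACACCAUGAAUAACCG
>api-miR-307 synthetic stand-in sequence
AAAAUAGUAGCAUAGGACACU
>dme-miR-8-5p synthetic stand-in sequence
AAUCGUUUCGCACUAAGCCAG
>anm-miR-9001 synthetic stand-in sequence
CCGGAAGACUAACAUCCUUUG
>anm-miR-9002 synthetic stand-in sequence
CCACCUAGCUUGACCCCAGUG
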