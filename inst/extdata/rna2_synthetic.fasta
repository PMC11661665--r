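>RNA2_synthetic_2774nt
AAAACUCCAUGUGUAACUCCGGAAGUAGAAUCUUGCACUCGGCCUUUCCAUAUCUCGUGAACCCCCUGCA
CGCCCUAAAGUACAAUUAGGAUAUUCAUCCCUACACUGUAUAUGCCGAACGUUCUAAUAAACGACUUAGC
AACAAGUCGCCUAGAAAGGUACCGCUGGCAUAUCACGCCUCCCGCUUGCCGUCUUCAACUUCAUGACCCU
CGUGCAUCACAAAGCCUCAAGCCGGAGUCUAGGCUUUGAAACAGCUGAAUAAAUCGUGUGAAUACGUGAG
UCGUCGGAAAGCAGUUGAAUAUCUAACGACCCCUGCGCAAGGACACACUAGUCGCCCUUGAGAGCACUCC
AGUCCAGGCGAGGUAUCCACGACGAUACGACUCGGCUAGCAAACGCGCGGUUUAUCUAUGCAGCUAAUAU
CCUUAGUAGUCGACCCCUGAGAUGACCGGUCAUCAGGCGGCAUCCGACGCACCAACGGCUCCUACAGACU
CGUGCUACCGGACCAUGCGACUCGAACAUCAGAUGGACAGACCUCGUAAUAGCCGGGCCAUGUAACACUG
AUGUCUCCGGGCAGCUCAUGACGAGCACCAGACCCGAGAGUUCCUGUUAGUUUUGGUUAGGCACGGAACG
CUAUCGAGCGCGUAAGCGCCAACCCGCAUUUACGAAGUACCCAUCGUAUGUAAUAAGACCUCGAGUACGU
CGGGACGUUGGCUGUGAUGUUUUGAUGAGCGAAGUUCGACGUUGCCGAUGUUUACCCUAAGGGAGACGAC
AUCAUCGCACGACUCGUCAUUUGCAUCAUCUCCACUGCCCCGAUGUCUGCUAUGGACGGCUUCACCUGAU
GUGGAGCGAGGGUACUGAUAGAUAUACGACAAUGCACGUAGUCUCGAUACGUCAUUGGUACGAACAGUUC
GUAUUCCCCAUGUCUGGACCGACGUUAAGCUCAUGUCUCAGGACGGAGAAUGCAGCCCAACAGCUUGGCC
GGAUCAAGCAGGAUGAGAGGCACUUACUUUCCCCGCUACGAUGCUUUGCACAAAUUCUACCGCAUUGAUC
GUGGAUUACUAGUUUUGAUGGCAUGGGUAAUGGUGGAGCCAAACAUCCAGCUAGCAGCUGCAAGCUUUGC
CUACGUGGAGUCUCUGUGAAAUUCAGAGAUACGCAGCUAAUGGCCCCGCUUAACGGGUGCAUCGGCACAG
CCUCGUGCAGCCCUCACAAAUUUCCGCCAUCAGUGAUUCAGUAUUGUUUCACCGCAGUUACCGUGAAGUG
CCGCCAUAUACACAGGUUCAUGCUAGAGAAACUGCCACCCGGGCUUGCCAACCGGCAACGUGGCGUUGAU
UGACAGAGCUUCUUAAGCCGCUGAUGUCCAAAAACUGAGUUAGUUCGAGAUAGUUGGAUGUCGCACUAGA
GGGAACAGCCAUAGGACCGAUACAGACAGUUCAAUGGCGGAUGCCCGCACCUGUAUACACCUAGUAUGUA
AAAAUUGAAUACGAGAGGGGCACCCUUUUGCCCUCCCACUGUCUAUUCCAGGUCGCCGAAUAUGUCCCGA
CUUCGACCCGUUUGGUAGGCCAGGGGCCUGGGCUAAACACGGCCUUCCCGAUUGCCAUGAACUCGUUUCG
CCUUAAAGUCCAACCGUAAAGAAGCGACAGCGACCUAAUCCGAGCUUUAUCUUUUAAGCGGGCGCGGGGA
UGGAGUCUAAGGCACAGACGGAUGCUCAUCAUAUCUCGUAGCAUUCAUAAUGUUGUGAAAAACGGAUAGG
CUGGGUCAACAGAUAUGUGUGGUAGAAUUACCGGCAGCUCUUUUGCCGGUGGGUGCCCGGCGACCCGAAA
CUCGGAUAUGCAUGGGGGAGGGCCACCCAUUUAUGUGCGAGCUGGAAGACGGUUCAGCGGUCCCUCUUUG
GAUCGAUUCCAAAUGACUAACUACGAGACGUGAGGCGUAUAGAAACUUAGCGCCGUAGCAGAGGAAUCAG
GAGAGGCUGGUAAAACUAAGUGUGAAGUAUAAAAUGCGGCGCAGUUUGGUAGACUCAUAGUAUAGGACGC
AUACUCUGAAGUUCGAAGCGGUUCCUUUUUGCUAAUUAACCAACAAGCCACGAGAGUUGUCCUCGUGUUU
CGCAGGGUAAAUGGACAUUUGCGGCCGCCGCUCAUGCUCGAUAUGAAUAAGUUCAGUGGGAUACCAUCGA
UCAGGGAAUCCCUAGGCCAGCGGAUAUCACAAUCCCUGUGGCACGGCAUGGUGGGCUCCCCUUAUCUUAG
GUUUAGUAGCACGCUGAUCCGCUCGAUGAGCAAAAGACCGACGCAGUCCGCGCUUCAUGCAGCUAAGUUA
UUAUUAAUCUUUCUCCAGGUUGGCUACGCUACCGUUCGGCAAACAUAUUGCUGCAAGAUACUAUUAGGUG
GCUGGACUUGGGCUAGUGGCCGACUGCUAAGUAUUCCCGUUUCAGUAUACUGACACGUGAAUCCACCAGG
GAAAACCUUAGUAGCGGCCCGGUAUAGCCAGCAUAGGGUAGUAAGGGAGGCCAUCAACGAUCGUGCGGUG
UGGAAUCCCAGAGAGGGUAGGAGGCUAAAGCUGUUGAGGGUAGGACUGACAGUGUGAGCGCGAAGGUCGU
GUCUUCGUUAGGCUGACGCACUAUACCACGUCAUACGCUAUCAUGAAUCUUCCUUGCUGUUGGGCUAAGC
GGGGAUCGCUUACGAGGUUAAAUCCCGCUCUUACAGGGAAGAGAGAGUCUUCCUUACUCGAGACCCAUAG
UACUAUGAUUUCGGGCAAAGAAGACGGGACCACUAAUAUUUGAC
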