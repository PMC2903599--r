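>t1
UCAUUCGGUUUUUUCGUUGUUCCAGUUUGUGGACCCGCAUCUGUGACGGGAACUUAUACC
>t2
UGAUUCGGCUGGUUACUUGUGACAGCUAGUGGACCUGCAUCUAUGACGGGCACAUAUACC
>t3
CGAUUCGGCAAUUACUAUGUAACUGCUUGUGCACCCACAUAUGUGGUGGGAAGAUAGACC
>t4
CGAUUCGGUAAGGUCUUUGUAACUACUUGUGCAUCAACAGCUGUGGUUGAUACACACACA
>t5
UUUUUCGGCUUGUUCCAUGUACCAGCUUGUGCACCCGCUUCUGUGGCGGGAAAAUACACC
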