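>miR-17-5p
CAAAGUGCUUACAGUGCAGGUAG
>miR-16-5p
UAGCAGCACGUAAAUAUUGGCG
>miR-21-5p
UAGCUUAUCAGACUGAUGUUGA
>miR-18a-5p
UAAGGUGCAUCUAGUGCAGAUAG
>miR-20a-5p
UAAAGUGCUUAUAGUGCAGGUAG
>miR-106a-5p
AAAAGUGCUUACAGUGCAGGUAG
>let-7a-5p
UGAGGUAGUAGGUUGUAUAGUU
>miR-206-3p
UGGAAUGUAAGGAAGUGUGUGG
>miR-1a-3p
UGGAAUGUAAAGAAGUAUGUAU
>miR-122-5p
UGGAGUGUGACAAUGGUGUUUG
>miR-10a-5p
UACCCUGUAGAUCCGAAUUUGUG
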