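>geneA synthetic example fragment
ACGTTGCAGGTCAACGGATCGGTTACGATCAGCTTAGCAGTCAGGCATTACGGACCAGTA
GGCATCAGTTTACCGAGGTACCGATCGGATTCAGCCATGGTACGTTAGCCGTATCAGGCA
>geneA_variant same fragment with two substitutions
ACGTTGCAGGTCAACGGATCGGTTACGATCAGCTTAGCAGTCAGGCATTACGGACCAGTA
GGCATCAGTTTACCGAGGTACCGATCGGATTCAGCCATCGTACGTTAGCCGTATCAGGAA
>geneB unrelated fragment with an ambiguous base
TTGACCATGCNGGACCTTAGCATCAGGATACCAGTTGACCATAGGCATCAGTTACGGATC
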