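>YHR179W_OYE2_synthetic synthetic stand-in CDS
ATGGAATTGAAAGATGTTATTGCCCAAAGAGGTTTCCCAGAATTGAAAGATGTTATTGCC
CAAAGAGGTTTCCCAGAATTGAAAGATGTTATTGCCCAAAGAGGTTTCCCAGAATTGAAA
GATGTTATTGCCCAAAGAGGTTTCCCAGAATTGAAAGATGTTATTGCCCAAAGAGGTTTC
CCAGAATTGAAAGATGTTATTGCCCAAAGAGGTTTCCCAGAATTGAAATCCGGTGCTGCT
GCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTAAGCCAGAATTGAAA
GATGTTATTGCCCAAAGAGGTTTCCCAGAATTGAAAGATGTTATTGCCCAAAGAGGTTTC
CCAGAATTGAAAGATGTTATTGCCCAAAGAGGTTTCCCAGAATTGAAAGATGTTATTGCC
CAAAGAGGTTTCCCAGAATTGAAAGATGTTATTGCCCAAAGAGGTTTCCCAGAATTGAAA
GATGTTATTGCCCAAAGAGGTTTCCCAGAATTGAAAGATGTTATTGCCCAAAGAGGTTTC
CCAGAATTGAAAGATGTTATTGCCCAAAGAGGTTTCCCAGAATTGAAAGATGTTATTGCC
CAAAGAGGTTTCCCAGAATTGAAAGATGTTATTGCCCAAAGAGGTTTCCCAGAATTGAAA
GATGTTATTGCCCAAAGAGGTTTCCCAGAATTGAAAGATGTTATTGCCCAAAGAGGTTTC
CCAGAATTGAAAGATGTTATTGCCCAAAGAGGTTTCCCAGAATTGAAAGATGTTATTGCC
CAAAGAGGTTTCCCAGAATTGAAAGATGTTATTGCCCAAAGAGGTTTCCCAGAATTGAAA
GATGTTATTGCCCAAAGAGGTTTCCCAGAATTGAAAGATGTTATTGCCCAAAGAGGTTTC
CCAGAATTGAAAGATGTTATTGCCCAAAGAGGTTTCCCAGAATTGAAAGATGTTATTGCC
CAAAGAGGTTTCCCAGAATTGAAAGATGTTATTGCCCAAAGAGGTTTCCCAGAATTGAAA
GATGTTATTGCCCAAAGAGGTTTCCCAGAATTGAAAGATGTTATTGCCCAAAGAGGTTTC
CCAGAATTGAAAGATGTTATTGCCCAAAGAGGTTTCCCAGAATTGAAAGATGTTATTGCC
CAAAGAGGTTTCCCAGAATTGAAAGATGTTATTGCCCAAAGAGGTTTCCCAGAATTGAAA
TAA
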