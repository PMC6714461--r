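>YDR247W_VHS1_synthetic synthetic stand-in CDS
ATGGAATTGAAAGATGTTATTGCCCAAAGAGGTTTCCCAGAATTGAAAGATGTTATTGCC
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
GATGTTATTGCCCAAAGAGGTTTCCCAGAATTGAAAGATGTTATTGCCCAAAGAGGTTTC
CCAGAATTGAAAGATGTTATTGCCCAAAGAGGTTTCCCAGAATTGAAAGATGTTATTGCC
CAAAGAGGTTTCCCAGAATTGAAAGATGTTATTGCCCAAAGAGGTTTCCCAGAATTGAAA
GATGTTATTGCCCAAAGAGGTTTCCCAGAATTGAAAGATGTTATTGCCCAAAGAGGTTTC
CCAGAATTGAAAGATGTTATTGCCCAAAGAGGTTACCCAGAATTGAAAGATGTTATTGCC
CAAAGAGGTTTCCCAGAATTGAAAGATGTTATTGCCCAAAGAGGTTTCCCAGAATTGAAA
GATGTTATTGCCCAAAGAGGTTTCCCAGAATTGAAAGATGTTATTGCCCAAAGAGGTTTC
CCAGAATTGAAAGATGTTATTGCCCAAAGAGGTTTCCCAGAATTGAAAGATGTTATTGCC
CAAAGAGGTTTCCCAGAATTGAAAGATGTTATTGCCCAAAGAGGTTTCCCAGAATTGAAA
GATTAA
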