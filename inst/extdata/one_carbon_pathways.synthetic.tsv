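gene	pathway
MTHFR	folate cycle
DHFR	folate cycle
MTHFD1	folate cycle
MTHFD1L	folate cycle
SHMT1	folate cycle
SHMT2	folate cycle
TYMS	folate cycle
ALDH1L1	folate cycle
FPGS	folate cycle
GART	folate cycle
FOLR1	folate biosynthesis
FOLR2	folate biosynthesis
FOLR3	folate biosynthesis
SLC19A1	folate biosynthesis
SLC46A1	folate biosynthesis
TCN1	folate biosynthesis
TCN2	folate biosynthesis
CUBN	folate biosynthesis
DHFR	folate biosynthesis
MTR	methionine cycle
MTRR	methionine cycle
MAT1A	methionine cycle
MAT2A	methionine cycle
MAT2B	methionine cycle
AHCY	methionine cycle
BHMT	methionine cycle
BHMT2	methionine cycle
GNMT	methionine cycle
AMD1	methionine cycle
DNMT1	methionine cycle
DNMT3A	methionine cycle
DNMT3B	methionine cycle
PEMT	methionine cycle
TYMS	methionine cycle
HIF3A	methionine cycle
CBS	cysteine and methionine metabolism
CTH	cysteine and methionine metabolism
AHCY	cysteine and methionine metabolism
MAT1A	cysteine and methionine metabolism
MAT2A	cysteine and methionine metabolism
PRMT3	transferring one-carbon groups
GNMT	transferring one-carbon groups
MTHFD1	transferring one-carbon groups
SHMT1	transferring one-carbon groups
GART	transferring one-carbon groups
DNMT1	transferring one-carbon groups
SHMT1	glycine, serine and threonine metabolism
SHMT2	glycine, serine and threonine metabolism
CHAT	glycine, serine and threonine metabolism
BHMT	glycine, serine and threonine metabolism
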