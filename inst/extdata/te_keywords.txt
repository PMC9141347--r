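# TE-relatedness vocabulary, one keyword per line.
# Matched case-insensitively at word boundaries against evidence
# descriptions and exon products. Edit freely; the list is data, not code.
reverse transcriptase
retrotranscriptase
ribonuclease h
rnase h
integrase
aspartyl protease
gag
pol
gag-pol
transposase
endonuclease
apurinic
gypsy
ty3
line
r2
retrotransposon
retrovirus
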