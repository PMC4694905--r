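>TOYPLUS
ATGCGCTGGCTGAAAGGCCCATAA
>TOYMINUS
ATGAAACCCGGGTTTTGATT
>TOYMINUS_CDS
ATGCGCAAACCCGGGTTTTGGTAA
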