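rank	experimental	simple_average	canonical_average
1	1BLF	9PAP	1BLF
2	1W0Q	1BLF	9PAP
3	9PAP	1AKI	1W0Q
4	3V03	3V03	3V03
5	1AKI	1AO6	1AKI
6	1AO6	1W0Q	1AO6
7	1FSX	1GZX	1GZX
8	1GZX	1FSX	1FSX
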