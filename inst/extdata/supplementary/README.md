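# External supplementary gene lists

The overlap check against the Rex reporter population lists needs four
plain-text gene lists (one gene id per line, `#` comment headers allowed)
that are not redistributable with this package. Obtain them from the
original study's supplementary data (SD1: the two priming lists; SD3: the
Rex population lists) and place them here as:

- `epi_priming.txt` — genes upregulated in the Epi-primed population (210)
- `pren_priming.txt` — genes upregulated in the PrEn-primed population (533)
- `rex_plus_up.txt` — genes upregulated in the Rex+ population
- `rex_minus_up.txt` — genes upregulated in the Rex− population

With the files present, the overlap test in
`tests/testthat/test-acceptance.R` computes `list_overlap_fisher()` on the
pairs (Epi, Rex+) and (PrEn, Rex−) and checks the printed counts (73 and
285). Without them that test fails with a message pointing here.
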