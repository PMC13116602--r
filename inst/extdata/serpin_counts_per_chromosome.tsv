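chromosome	n_genes	n_unique
Chr1	4	4
Chr2	2	1
Chr3	2	2
Chr4	2	2
Chr5	6	4
Chr10	50	49
Chr11	6	6
Chr13	1	1
JAMZAT010000234.1	1	1
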