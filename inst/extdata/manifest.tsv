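file	md5
crc_mapk_cohort.tsv	ba7fefde4ed2e8fd2daca1bf2547b683
crc_mapk_de_genes.tsv	2c5e61e1c28831030e1855d798dd5bb7
crc_mapk_mirna_assoc.tsv	85d2df1d18ab13ebb94c73d10a4c050f
crc_mapk_seed_summary.tsv	b51290b8c4577b9f0dc5bc92c1f5096e
crc_mapk_subgroup_genes.tsv	70f4fb1801547679a5592504a9ce9ee6
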