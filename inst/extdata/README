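brca_reported_genes.tsv / luad_reported_genes.tsv

Published per-gene summary rows for the top CNA-driven genes reported in a
breast-cancer cohort and a lung-adenocarcinoma cohort (group expression
means after baseline centering, CNA proportions, test p-value and FDR).
The raw cohort data are not distributed; these summary rows serve as a
worked example and as a consistency check of the pooled-complement
GE_mean_diff statistic (see reconstructGroupDiff()). NA marks a group with
no samples. Values are printed to the precision of the source tables.
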