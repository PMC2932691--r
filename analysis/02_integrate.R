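#!/usr/bin/env Rscript
# Stage 2: integrate proteome and genome into a matched per-gene table.
#
# Protein ratios against the internal standard are collapsed to
# log2(tumor/control) by the ratio-of-ratios, filtered to >= 2
# quantification events per experiment, and triplicates are combined by
# the median. Probe smooth signals are summarized to per-gene copy
# numbers (median over probes) and normalized to the diploid control.
# The two sides are joined on the gene name, and the headline per-gene
# correlation between copy-number change and protein change is computed.

library(proteocna)

proteins <- read_tsv_c("results/data/proteins.tsv")
tumor <- read_tsv_c("results/data/tumor_probes.tsv")
control <- read_tsv_c("results/data/control_probes.tsv")

matched <- integrate_datasets(proteins, tumor, control, min_events = 2,
                              center = TRUE)
write_tsv_c(matched, "results/matched.tsv")

cr <- correlation_and_r2(matched)
message(sprintf("matched genes: %d", nrow(matched)))
message(sprintf("raw per-gene Pearson r (copy vs protein): %.2f", cr$r))
message(sprintf("variance of protein change explained by copy change: %.1f%%",
                cr$r2_percent))
message("wrote results/matched.tsv")
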