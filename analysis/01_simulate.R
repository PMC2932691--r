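#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data.
#
# Emulates the measured structure of an aneuploid breast-cancer line
# profiled against a diploid control: a segmented tumor genome observed
# through noisy SNP-array smooth signals (diploid control peaking at 2),
# a SILAC-style protein table quantified as ratios against a common
# internal standard, and random annotation terms with one planted
# proteome-shifted category. Attenuation is set so that only a few percent
# of protein variance is dosage-driven, the regime the downstream
# profiling is designed for.

library(proteocna)

out_dir <- "results/data"
cfg <- sim_config(
  n_chromosomes = 10, genes_per_chromosome = 300,
  segment_mean_length = 40,
  copy_states = c("1" = 0.08, "2" = 0.72, "3" = 0.12, "4" = 0.08),
  probe_noise_sd = 0.2,
  attenuation_alpha = 0.12, protein_noise_sd = 0.3,
  dosage_sensitive_fraction = 1,
  n_terms = 60, term_size_range = c(10L, 50L),
  n_planted_terms = 1, planted_term_shift = c(copy = 0, protein = 1),
  seed = 17L
)
dataset <- simulate_dataset(cfg, n_replicates = 3L)
write_sim_dataset(dataset, out_dir)

mode <- control_diploidy_check(dataset$control_probes)
message(sprintf("control smooth-signal mode: %.2f (diploid expectation 2)",
                mode))
aberrant <- with(dataset$truth$segments, sum((end - start + 1)[copy_state != 2]))
message(sprintf("simulated %d genes, %d (%.0f%%) in non-diploid segments",
                nrow(dataset$truth$genes), aberrant,
                100 * aberrant / nrow(dataset$truth$genes)))
message("planted proteome-shifted term: ",
        names(dataset$truth$planted_terms)[1])
message("wrote ", out_dir)
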