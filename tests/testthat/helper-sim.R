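# Shared fixture builders. All data is generated in code at test time.

# Small matched table with independent Gaussian dimensions.
make_matched <- function(n, seed = 1, sd_copy = 0.5, sd_prot = 0.5) {
  set.seed(seed)
  data.frame(
    gene = sprintf("g%04d", seq_len(n)),
    chromosome = paste0("chr", rep_len(1:4, n)),
    position = rep_len(seq(1, by = 10000, length.out = ceiling(n / 4)),
                       n),
    copy_log2 = rnorm(n, sd = sd_copy),
    protein_log2 = rnorm(n, sd = sd_prot),
    stringsAsFactors = FALSE
  )
}

# Study conditions for the profiling benchmarks: 5 chromosomes x 300
# genes, 6 planted segments of 15-60 genes at |mean| 0.6-1.5 log2,
# protein noise sd 0.3.
recovery_run <- function(seed) {
  segs <- plant_segments(5, 300, n_segments = 6,
                         length_range = c(15, 60),
                         mean_range = c(0.6, 1.5), seed = 1000 + seed)
  tr <- simulate_protein_track(5, 300, segs, noise_sd = 0.3,
                               seed = 2000 + seed)
  ap <- genome_profile(tr, fdr = 0.02, n_permutations = 10,
                       seed = 3000 + seed)
  list(segs = segs, track = tr, ap = ap)
}

# For each planted segment: was the maximal same-sign nonzero run
# containing its midpoint sign-correct, and what is its boundary error?
segment_recovery <- function(segs, ap) {
  runs <- profile_segments(ap)
  t(vapply(seq_len(nrow(segs)), function(i) {
    mid <- floor((segs$start[i] + segs$end[i]) / 2)
    r <- runs[runs$chromosome == segs$chromosome[i] &
                runs$start_index < mid & runs$end_index >= mid, ,
              drop = FALSE]
    if (nrow(r) == 0) return(c(sign_ok = 0, err = Inf))
    c(sign_ok = as.numeric((r$call[1] == "amp") == (segs$mean[i] > 0)),
      err = max(abs(r$start_index[1] + 1 - segs$start[i]),
                abs(r$end_index[1] - segs$end[i])))
  }, c(sign_ok = 0, err = 0)))
}

# Frozen configuration for the correlation-amplification benchmark:
# arm-level events, full dosage sensitivity at attenuation 0.5, protein
# noise chosen by the closed form so the raw per-gene Pearson r is ~0.25.
corr_amp_config <- function(seed) {
  sim_config(n_chromosomes = 10, genes_per_chromosome = 300,
             segment_mean_length = 60,
             copy_states = c("1" = 0.08, "2" = 0.80, "4" = 0.12),
             attenuation_alpha = 0.5, protein_noise_sd = 0.82,
             dosage_sensitive_fraction = 1, n_terms = 0, seed = seed)
}

corr_amp_run <- function(seed) {
  d <- simulate_dataset(corr_amp_config(seed))
  m <- suppressWarnings(suppressMessages(
    integrate_datasets(d$proteins, d$tumor_probes, d$control_probes)))
  raw <- correlation_and_r2(m)$r
  tr <- data.frame(gene = m$gene, chromosome = m$chromosome,
                   position = m$position, log2_ratio = m$protein_log2)
  ap <- genome_profile(tr, seed = seed + 500)
  prof <- profiled_correlation(ap$profile$profile_value,
                               m$copy_log2[match(ap$profile$gene, m$gene)])
  c(raw = raw, prof = prof)
}

# Null-term empirical FDP at BH 0.05: random memberships on independent
# Gaussian dimensions; every rejection is false by construction.
null_term_fdp <- function(seed, n = 2000, n_terms = 1000,
                          size_range = c(10, 50)) {
  m <- make_matched(n, seed = seed)
  ranks <- rank_dimensions(m)
  set.seed(seed + 7)
  p <- vapply(seq_len(n_terms), function(i) {
    mem <- rep(FALSE, n)
    mem[sample.int(n, sample(seq(size_range[1], size_range[2]), 1))] <- TRUE
    mannwhitney_2d(mem, ranks)$p_value
  }, numeric(1))
  rej <- sum(bh_adjust(p, fdr = 0.05)$significant)
  ifelse(rej > 0, 1, 0)  # pure null: FDP = V/max(R,1) is 1 iff any rejection
}
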