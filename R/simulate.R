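#' Simulation configuration for synthetic proteogenomic data
#'
#' Bundles and validates every parameter of the synthetic-data generator.
#' The generator emulates the statistical structure the downstream analysis
#' assumes: a diploid control whose SNP-array smooth signal peaks at 2,
#' an aneuploid tumor genome made of segments at integer copy states,
#' and a proteome whose log2 ratios respond to gene dosage only partially
#' (attenuation), so that only a small share of protein variance is
#' explained by copy-number change.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param genes_per_chromosome Genes per chromosome, ordered by position.
#' @param probes_per_gene SNP-array probes annotated to each gene.
#' @param segment_mean_length Mean segment length in genes; segment lengths
#'   are geometric, the simplest stationary model producing both focal
#'   amplicons and arm-level events.
#' @param copy_states Named numeric vector of sampling weights for integer
#'   copy states; names are the states ("0", "1", ...). The diploid state 2
#'   must dominate for the control-normalization logic to make sense.
#' @param probe_noise_sd Gaussian sd of the smooth signal around its
#'   integer copy state, in smooth-signal units.
#' @param dosage_sensitive_fraction Fraction of genes whose protein level
#'   follows gene dosage at all; the rest are fully buffered.
#' @param attenuation_alpha Dosage-response coefficient in [0, 1] for
#'   dosage-sensitive genes: protein log2 ratio gains
#'   `alpha * log2(copy/2)`.
#' @param protein_noise_sd Gaussian sd of protein log2 ratios, log2 units.
#' @param n_terms Number of random annotation terms to generate.
#' @param term_size_range Integer range of term sizes.
#' @param planted_term_shift Length-2 numeric `c(copy, protein)`: log2
#'   shifts applied to members of planted terms in each dimension.
#' @param n_planted_terms How many of the terms receive the planted shift.
#' @param single_event_fraction Fraction of protein records whose
#'   quantification-event count is 1 (to exercise the min-events filter).
#' @param log2_zero_floor Value substituted for `log2(0/2)` when a gene has
#'   copy state 0; keeps downstream t-tests finite and mimics residual
#'   protein from incomplete loss.
#' @param seed Integer seed; together with the other fields it fully
#'   determines the generator output.
#'
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_chromosomes = 5,
                       genes_per_chromosome = 300,
                       probes_per_gene = 3,
                       segment_mean_length = 25,
                       copy_states = c("1" = 0.08, "2" = 0.72, "3" = 0.12, "4" = 0.08),
                       probe_noise_sd = 0.2,
                       dosage_sensitive_fraction = 1,
                       attenuation_alpha = 0.18,
                       protein_noise_sd = 0.3,
                       n_terms = 50,
                       term_size_range = c(10L, 50L),
                       planted_term_shift = c(copy = 0, protein = 0),
                       n_planted_terms = 0,
                       single_event_fraction = 0.1,
                       log2_zero_floor = -5,
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    genes_per_chromosome = as.integer(genes_per_chromosome),
    probes_per_gene = as.integer(probes_per_gene),
    segment_mean_length = segment_mean_length,
    copy_states = copy_states,
    probe_noise_sd = probe_noise_sd,
    dosage_sensitive_fraction = dosage_sensitive_fraction,
    attenuation_alpha = attenuation_alpha,
    protein_noise_sd = protein_noise_sd,
    n_terms = as.integer(n_terms),
    term_size_range = as.integer(term_size_range),
    planted_term_shift = planted_term_shift,
    n_planted_terms = as.integer(n_planted_terms),
    single_event_fraction = single_event_fraction,
    log2_zero_floor = log2_zero_floor,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_chromosomes >= 1, cfg$genes_per_chromosome >= 1,
    cfg$probes_per_gene >= 1, cfg$segment_mean_length >= 1,
    cfg$probe_noise_sd >= 0, cfg$protein_noise_sd >= 0,
    cfg$dosage_sensitive_fraction >= 0, cfg$dosage_sensitive_fraction <= 1,
    cfg$attenuation_alpha >= 0, cfg$attenuation_alpha <= 1,
    cfg$single_event_fraction >= 0, cfg$single_event_fraction <= 1,
    cfg$n_terms >= 0, length(cfg$term_size_range) == 2,
    cfg$term_size_range[1] >= 1,
    cfg$term_size_range[1] <= cfg$term_size_range[2],
    length(cfg$planted_term_shift) == 2,
    cfg$n_planted_terms >= 0, cfg$n_planted_terms <= cfg$n_terms,
    all(names(cfg$copy_states) != ""), all(cfg$copy_states >= 0),
    sum(cfg$copy_states) > 0,
    all(as.integer(names(cfg$copy_states)) >= 0)
  )
  names(cfg$planted_term_shift) <- c("copy", "protein")
  class(cfg) <- "sim_config"
  cfg
}

# gene positions: synthetic integers 10 kb apart; probes 1 kb apart within a
# gene. Only the ordering matters downstream.
.gene_position <- function(i) (i - 1L) * 10000L + 1L

# sample from the elements of v (safe for length-1 v, unlike sample())
.resample <- function(v, size, replace = FALSE, prob = NULL) {
  v[sample.int(length(v), size, replace = replace, prob = prob)]
}

#' Simulate a segmented tumor genome and its diploid control
#'
#' Draws segment boundaries per chromosome (geometric lengths), assigns each
#' segment an integer copy state, and emits probe-level smooth-signal tables
#' for the tumor (signal centered on the segment copy state) and for the
#' control (centered on 2, diploid). Negative noise excursions are clamped
#' at 0 because smooth signals are non-negative.
#'
#' @param cfg A [sim_config()].
#' @param seed Seed for this step; defaults to `cfg$seed`.
#' @return A list with `truth` (gene table with the true copy state and the
#'   segment table), `tumor_probes` and `control_probes` (data frames with
#'   columns chromosome, position, gene, smooth_signal).
#' @export
simulate_genome <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  states <- as.integer(names(cfg$copy_states))
  w <- cfg$copy_states / sum(cfg$copy_states)

  genes_list <- vector("list", cfg$n_chromosomes)
  seg_list <- vector("list", cfg$n_chromosomes)
  for (ch in seq_len(cfg$n_chromosomes)) {
    L <- cfg$genes_per_chromosome
    lens <- integer(0)
    while (sum(lens) < L) {
      lens <- c(lens, stats::rgeom(50L, prob = 1 / cfg$segment_mean_length) + 1L)
    }
    cum <- cumsum(lens)
    nseg <- which(cum >= L)[1]
    lens <- lens[seq_len(nseg)]
    lens[nseg] <- lens[nseg] - (cum[nseg] - L)
    seg_state <- .resample(states, nseg, replace = TRUE, prob = w)
    chrom <- paste0("chr", ch)
    starts <- cumsum(c(1L, lens[-nseg]))
    ends <- cumsum(lens)
    seg_list[[ch]] <- data.frame(
      chromosome = chrom, start = starts, end = ends,
      copy_state = seg_state, stringsAsFactors = FALSE
    )
    genes_list[[ch]] <- data.frame(
      gene = sprintf("G%d_%04d", ch, seq_len(L)),
      chromosome = chrom,
      position = .gene_position(seq_len(L)),
      copy_state = rep(seg_state, lens),
      stringsAsFactors = FALSE
    )
  }
  genes <- do.call(rbind, genes_list)
  segments <- do.call(rbind, seg_list)

  k <- cfg$probes_per_gene
  n <- nrow(genes)
  probe_pos <- rep(genes$position, each = k) + rep(0:(k - 1), times = n) * 1000L
  probes <- data.frame(
    chromosome = rep(genes$chromosome, each = k),
    position = probe_pos,
    gene = rep(genes$gene, each = k),
    stringsAsFactors = FALSE
  )
  tumor <- probes
  tumor$smooth_signal <- pmax(0, rep(genes$copy_state, each = k) +
    stats::rnorm(n * k, sd = cfg$probe_noise_sd))
  control <- probes
  control$smooth_signal <- pmax(0, 2 + stats::rnorm(n * k, sd = cfg$probe_noise_sd))

  truth <- list(
    genes = genes, segments = segments,
    protein_shift = stats::setNames(numeric(n), genes$gene),
    copy_shift = stats::setNames(numeric(n), genes$gene),
    planted_terms = list(), seed = seed
  )
  class(truth) <- "sim_truth"
  list(truth = truth, tumor_probes = tumor, control_probes = control)
}

#' Simulate random annotation terms, optionally planting shifted categories
#'
#' Samples `n_terms` gene sets from the simulated universe with sizes drawn
#' uniformly from `term_size_range`. The first `n_planted_terms` terms are
#' marked as planted: their members receive the configured log2 shifts in
#' the copy dimension (applied to the tumor probe signals by
#' [simulate_dataset()]) and the protein dimension (applied by
#' [simulate_proteome()]). Membership is recorded in the truth object.
#'
#' @param truth A `sim_truth` from [simulate_genome()].
#' @param cfg The [sim_config()].
#' @param seed Seed for this step; defaults to `cfg$seed + 1`.
#' @return A list with `terms` (named list of member gene vectors, with a
#'   `source` attribute) and the updated `truth`.
#' @export
simulate_annotations <- function(truth, cfg, seed = cfg$seed + 1L) {
  stopifnot(inherits(truth, "sim_truth"), inherits(cfg, "sim_config"))
  set.seed(seed)
  universe <- truth$genes$gene
  terms <- list()
  if (cfg$n_terms > 0) {
    if (cfg$term_size_range[2] > length(universe)) {
      stop("term sizes exceed the gene universe")
    }
    sizes <- .resample(seq(cfg$term_size_range[1], cfg$term_size_range[2]),
                      cfg$n_terms, replace = TRUE)
    terms <- lapply(sizes, function(m) sample(universe, m))
    names(terms) <- sprintf("TERM%04d", seq_len(cfg$n_terms))
  }
  attr(terms, "source") <- rep("SIM", length(terms))
  if (cfg$n_planted_terms > 0) {
    planted <- names(terms)[seq_len(cfg$n_planted_terms)]
    truth$planted_terms <- terms[planted]
    members <- unique(unlist(terms[planted]))
    truth$protein_shift[members] <- truth$protein_shift[members] +
      cfg$planted_term_shift[["protein"]]
    truth$copy_shift[members] <- truth$copy_shift[members] +
      cfg$planted_term_shift[["copy"]]
  }
  list(terms = terms, truth = truth)
}

#' Simulate a SILAC-style protein quantification table
#'
#' Protein log2 ratio (tumor vs control) for gene g is
#' `alpha_g * log2(c_g / 2) + planted term shift + N(0, protein_noise_sd)`,
#' where `alpha_g = attenuation_alpha` for dosage-sensitive genes and 0
#' otherwise, and `log2(0/2)` is floored at `cfg$log2_zero_floor`. The
#' table is emitted as two ratios against a common internal standard, so
#' that the ratio-of-ratios reader recovers the simulated log2 value.
#'
#' @param truth A `sim_truth` (after [simulate_annotations()] if planted
#'   terms are wanted).
#' @param cfg The [sim_config()].
#' @param n_replicates Number of biological replicates to emit.
#' @param seed Seed for this step; defaults to `cfg$seed + 2`.
#' @return A data frame with columns gene, chromosome, position,
#'   ratio_tumor_vs_std, ratio_control_vs_std, n_events, replicate.
#' @export
simulate_proteome <- function(truth, cfg, n_replicates = 1L,
                              seed = cfg$seed + 2L) {
  stopifnot(inherits(truth, "sim_truth"), inherits(cfg, "sim_config"))
  set.seed(seed)
  genes <- truth$genes
  n <- nrow(genes)
  sensitive <- stats::runif(n) < cfg$dosage_sensitive_fraction
  alpha_g <- ifelse(sensitive, cfg$attenuation_alpha, 0)
  dose <- ifelse(genes$copy_state == 0, cfg$log2_zero_floor,
                 log2(genes$copy_state / 2))
  mu <- alpha_g * dose + truth$protein_shift[genes$gene]
  reps <- lapply(seq_len(n_replicates), function(r) {
    value <- mu + stats::rnorm(n, sd = cfg$protein_noise_sd)
    ctrl <- 2^stats::rnorm(n, sd = 0.1)
    n_events <- ifelse(stats::runif(n) < cfg$single_event_fraction, 1L,
                       2L + stats::rpois(n, 3))
    data.frame(
      gene = genes$gene, chromosome = genes$chromosome,
      position = genes$position,
      ratio_tumor_vs_std = ctrl * 2^value,
      ratio_control_vs_std = ctrl,
      n_events = n_events, replicate = r,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, reps)
  attr(out, "true_mean") <- stats::setNames(mu, genes$gene)
  attr(out, "alpha_g") <- stats::setNames(alpha_g, genes$gene)
  out
}

#' Simulate a complete proteogenomic dataset
#'
#' Convenience wrapper running [simulate_genome()], [simulate_annotations()]
#' and [simulate_proteome()] with seeds derived from `cfg$seed`, and applying
#' any planted copy-dimension shift to the tumor probe signals
#' (multiplicative, `signal * 2^shift`).
#'
#' @param cfg A [sim_config()].
#' @param n_replicates Replicates for the proteome table.
#' @return A list with `truth`, `tumor_probes`, `control_probes`,
#'   `proteins`, `terms`.
#' @export
simulate_dataset <- function(cfg, n_replicates = 1L) {
  g <- simulate_genome(cfg)
  a <- simulate_annotations(g$truth, cfg)
  truth <- a$truth
  shift <- truth$copy_shift[g$tumor_probes$gene]
  g$tumor_probes$smooth_signal <- g$tumor_probes$smooth_signal * 2^shift
  proteins <- simulate_proteome(truth, cfg, n_replicates = n_replicates)
  list(truth = truth, tumor_probes = g$tumor_probes,
       control_probes = g$control_probes, proteins = proteins,
       terms = a$terms)
}

#' Simulate a per-gene protein log-ratio track with planted segments
#'
#' Lower-level generator used to study the genome-profiling algorithm in
#' isolation: a Gaussian log2-ratio track over ordered genes, with optional
#' contiguous segments of non-zero mean (regional amplification or deletion
#' signatures at the protein level).
#'
#' @param n_chromosomes,genes_per_chromosome Grid dimensions.
#' @param segments `NULL` for a pure-null track, or a data frame with
#'   columns chromosome (e.g. "chr1"), start, end (1-based gene indices,
#'   inclusive) and mean (log2 shift of the segment).
#' @param noise_sd Gaussian noise sd in log2 units.
#' @param seed Integer seed.
#' @return A data frame with gene, chromosome, position, log2_ratio, plus a
#'   `true_mean` column carrying the planted regional mean.
#' @export
simulate_protein_track <- function(n_chromosomes, genes_per_chromosome,
                                   segments = NULL, noise_sd = 0.3,
                                   seed = 1L) {
  stopifnot(n_chromosomes >= 1, genes_per_chromosome >= 1, noise_sd >= 0)
  set.seed(seed)
  L <- genes_per_chromosome
  track <- data.frame(
    gene = sprintf("G%d_%04d", rep(seq_len(n_chromosomes), each = L),
                   rep(seq_len(L), n_chromosomes)),
    chromosome = paste0("chr", rep(seq_len(n_chromosomes), each = L)),
    position = rep(.gene_position(seq_len(L)), n_chromosomes),
    true_mean = 0,
    stringsAsFactors = FALSE
  )
  if (!is.null(segments) && nrow(segments) > 0) {
    stopifnot(all(c("chromosome", "start", "end", "mean") %in% names(segments)),
              all(segments$start >= 1), all(segments$end <= L),
              all(segments$start <= segments$end))
    for (i in seq_len(nrow(segments))) {
      sel <- track$chromosome == segments$chromosome[i]
      idx <- which(sel)[segments$start[i]:segments$end[i]]
      track$true_mean[idx] <- track$true_mean[idx] + segments$mean[i]
    }
  }
  track$log2_ratio <- track$true_mean +
    stats::rnorm(nrow(track), sd = noise_sd)
  track
}

#' Place non-overlapping segments at random on a simulated gene grid
#'
#' Samples segment lengths and absolute means uniformly from the given
#' ranges, signs at random, and positions them with a guard gap so that
#' segments neither touch each other nor the chromosome ends. Used to set
#' up recovery benchmarks for the profiling algorithm.
#'
#' @param n_chromosomes,genes_per_chromosome Grid dimensions.
#' @param n_segments Number of segments to plant.
#' @param length_range Inclusive integer range of segment lengths (genes).
#' @param mean_range Range of |segment mean| in log2 units.
#' @param gap Minimum distance (genes) between segments and from the
#'   chromosome ends.
#' @param seed Integer seed.
#' @return A segments data frame suitable for [simulate_protein_track()].
#' @export
plant_segments <- function(n_chromosomes, genes_per_chromosome,
                           n_segments = 6, length_range = c(15, 60),
                           mean_range = c(0.6, 1.5), gap = 25, seed = 1L) {
  set.seed(seed)
  segs <- data.frame(chromosome = character(0), start = integer(0),
                     end = integer(0), mean = numeric(0),
                     stringsAsFactors = FALSE)
  tries <- 0
  while (nrow(segs) < n_segments) {
    tries <- tries + 1
    if (tries > 10000) stop("cannot place segments; grid too small")
    len <- .resample(seq(length_range[1], length_range[2]), 1)
    chrom <- paste0("chr", sample(n_chromosomes, 1))
    start <- .resample(seq(1 + gap, genes_per_chromosome - len - gap), 1)
    end <- start + len - 1L
    same <- segs[segs$chromosome == chrom, , drop = FALSE]
    if (nrow(same) > 0 &&
        any(start <= same$end + gap & end >= same$start - gap)) next
    m <- stats::runif(1, mean_range[1], mean_range[2]) *
      sample(c(-1, 1), 1)
    segs <- rbind(segs, data.frame(chromosome = chrom, start = start,
                                   end = end, mean = m,
                                   stringsAsFactors = FALSE))
  }
  segs[order(segs$chromosome, segs$start), ]
}
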