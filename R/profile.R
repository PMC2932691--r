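#' Multi-scale window sizes for one chromosome
#'
#' Window sizes grow from 3 genes to the whole chromosome in steps of
#' factors of sqrt(2): `s_k = round(3 * sqrt(2)^k)`, deduplicated, capped
#' at the chromosome length, with the chromosome length itself always
#' included.
#'
#' @param chromosome_length Number of position-ordered genes on the
#'   chromosome; must be at least 3.
#' @return Increasing integer vector of window sizes.
#' @export
window_sizes <- function(chromosome_length) {
  stopifnot(chromosome_length >= 3)
  k <- 0:ceiling(2 * log2(chromosome_length))
  s <- round(3 * sqrt(2)^k)
  s <- s[s <= chromosome_length]
  sort(unique(c(s, chromosome_length)))
}

# Vectorized one-sample t-tests for all windows of one size over a track.
# Returns start index (1-based), mean, sd, p. Zero-variance convention:
# p = 1 when the mean is 0 (no deviation to call), the smallest
# representable positive p when the mean is nonzero (a flat shifted window
# is unambiguous evidence).
.scan_one_size <- function(x, s) {
  L <- length(x)
  nw <- L - s + 1L
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  sums <- cs[(s + 1):(L + 1)] - cs[1:nw]
  sums2 <- cs2[(s + 1):(L + 1)] - cs2[1:nw]
  means <- sums / s
  vars <- pmax(0, (sums2 - sums^2 / s) / (s - 1))
  sds <- sqrt(vars)
  tt <- means / (sds / sqrt(s))
  p <- 2 * stats::pt(-abs(tt), df = s - 1)
  zerovar <- sds == 0
  if (any(zerovar)) {
    p[zerovar & means == 0] <- 1
    p[zerovar & means != 0] <- .Machine$double.xmin
  }
  p <- pmax(p, .Machine$double.xmin)
  list(start = seq_len(nw), mean = means, sd = sds, p = p)
}

# Window medians for all windows of one size (order-invariant, so the
# column reversal done by embed() is irrelevant).
.window_medians <- function(x, s) {
  if (s == length(x)) return(stats::median(x))
  apply(embed(x, s), 1, stats::median)
}

#' Scan one chromosome with sliding windows at every size
#'
#' Windows of each size are moved along the position-ordered log2-ratio
#' track with stride 1, and the deviation of each window mean from zero is
#' tested with a two-sided one-sample t-test. Windows never span
#' chromosome boundaries.
#'
#' @param x Numeric vector of per-gene log2 ratios, ordered by position.
#' @param sizes Window sizes, typically [window_sizes()] of `length(x)`.
#' @param medians Compute window medians too (needed for the observed
#'   genome, skippable for permuted genomes).
#' @return Data frame with one row per window: start_index, end_index
#'   (0-based half-open), size, mean, median (NA when not computed),
#'   p_value.
#' @export
scan_chromosome <- function(x, sizes = window_sizes(length(x)),
                            medians = TRUE) {
  stopifnot(length(x) >= 3, all(is.finite(x)), all(sizes >= 3),
            all(sizes <= length(x)))
  out <- lapply(sizes, function(s) {
    sc <- .scan_one_size(x, s)
    data.frame(
      start_index = sc$start - 1L,
      end_index = sc$start - 1L + s,
      size = s,
      mean = sc$mean,
      median = if (medians) .window_medians(x, s) else NA_real_,
      p_value = sc$p
    )
  })
  do.call(rbind, out)
}

#' Permute a log-ratio track genome-wide
#'
#' Produces one "randomized genome": the multiset of values is preserved
#' exactly and only their assignment to positions changes, so the null
#' retains the global value distribution while destroying regional
#' structure.
#'
#' @param x Numeric vector of log2 ratios (all chromosomes concatenated in
#'   position order).
#' @param seed Optional integer seed for this permutation.
#' @return Permuted numeric vector of the same length.
#' @export
randomize_genome <- function(x, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x[sample.int(length(x))]
}

#' Transform window p-values to posterior error probabilities
#'
#' Applies Bayes' rule to two-dimensional histograms of (log10 p, window
#' size): within each window-size stratum, p-values of observed and
#' permuted windows are binned on log10 p (20 bins spanning their joint
#' range), and the PEP of a bin is the ratio of the expected null count
#' per genome to the observed count, with the null prior pi0 fixed at 1
#' (conservative). Null counts carry a +1 smoothing so a permutation
#' estimate is never exactly zero; bins with no observed window inherit the
#' PEP of the nearest populated bin; finally PEPs are monotonized to be
#' non-increasing in -log10 p within each size stratum.
#'
#' @param obs Observed window table from [scan_chromosome()] (any number of
#'   chromosomes row-bound; must have size and p_value).
#' @param null_p List (length = number of permutations) of numeric vectors
#'   of null window p-values, each element aligned with `obs` rows
#'   (same window structure per permuted genome).
#' @param n_bins Number of log10-p bins per size stratum.
#' @return List with `pep_obs` (numeric per observed window) and
#'   `pep_null` (matrix, windows x permutations).
#' @export
pep_transform <- function(obs, null_p, n_bins = 20) {
  n_perm <- length(null_p)
  stopifnot(n_perm >= 1)
  null_mat <- do.call(cbind, null_p)
  stopifnot(nrow(null_mat) == nrow(obs))
  pep_obs <- rep(NA_real_, nrow(obs))
  pep_null <- matrix(NA_real_, nrow(obs), n_perm)
  for (s in unique(obs$size)) {
    sel <- obs$size == s
    lp_o <- log10(obs$p_value[sel])
    lp_n <- log10(null_mat[sel, , drop = FALSE])
    rng <- range(c(lp_o, lp_n))
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
    bin_o <- findInterval(lp_o, edges, rightmost.closed = TRUE,
                          all.inside = TRUE)
    bin_n <- findInterval(lp_n, edges, rightmost.closed = TRUE,
                          all.inside = TRUE)
    cnt_o <- tabulate(bin_o, nbins = n_bins)
    cnt_n <- tabulate(bin_n, nbins = n_bins)
    pep_bin <- ifelse(cnt_o > 0,
                      pmin(1, ((cnt_n + 1) / n_perm) / cnt_o),
                      NA_real_)
    # empty observed bins inherit from the nearest populated bin
    if (anyNA(pep_bin)) {
      filled <- which(!is.na(pep_bin))
      for (b in which(is.na(pep_bin))) {
        pep_bin[b] <- pep_bin[filled[which.min(abs(filled - b))]]
      }
    }
    # non-increasing in -log10 p: small-p bins never exceed large-p bins
    pep_bin <- rev(cummin(rev(pep_bin)))
    pep_obs[sel] <- pep_bin[bin_o]
    pep_null[sel, ] <- pep_bin[bin_n]
  }
  list(pep_obs = pep_obs, pep_null = pep_null)
}

#' Permutation-based FDR threshold on window PEPs
#'
#' Finds the largest PEP cutoff t such that the estimated false discovery
#' rate — the mean number of permuted-genome windows at PEP <= t (with a
#' +1 smoothing, so an empty null never certifies an FDR of exactly zero)
#' divided by the number of observed windows at PEP <= t — does not exceed
#' `fdr`.
#'
#' @param pep_obs Numeric PEPs of observed windows.
#' @param pep_null Matrix of PEPs of permuted windows (windows x
#'   permutations).
#' @param fdr Target false discovery rate (default 0.02).
#' @return List with `cutoff` (-Inf when nothing passes), `significant`
#'   (logical per observed window) and `fdr_at_cutoff`.
#' @export
significance_threshold <- function(pep_obs, pep_null, fdr = 0.02) {
  stopifnot(fdr >= 0, fdr <= 1)
  n_perm <- ncol(pep_null)
  cand <- sort(unique(pep_obs))
  null_sorted <- sort(as.numeric(pep_null))
  R <- findInterval(cand, sort(pep_obs))          # observed windows <= t
  V <- findInterval(cand, null_sorted)            # null windows <= t (all perms)
  fdr_hat <- ((V + 1) / n_perm) / R
  ok <- which(fdr_hat <= fdr)
  if (length(ok) == 0 || fdr == 0) {
    return(list(cutoff = -Inf, significant = rep(FALSE, length(pep_obs)),
                fdr_at_cutoff = NA_real_))
  }
  cutoff <- cand[max(ok)]
  list(cutoff = cutoff, significant = pep_obs <= cutoff,
       fdr_at_cutoff = fdr_hat[max(ok)])
}

#' Build the amplification/deletion profile from significant windows
#'
#' At each gene position every intersecting significant window is
#' considered and the window median that deviates most from zero is taken;
#' positions intersected by no significant window get exactly 0. Ties in
#' |median| are broken in favor of the smaller (shorter) window.
#'
#' @param sig Data frame of significant windows with chromosome,
#'   start_index, end_index (0-based half-open, per chromosome), size,
#'   median.
#' @param gene_order Data frame of all profiled genes with chromosome (and
#'   one row per gene in position order within chromosome).
#' @return Numeric vector `profile_value` per gene of `gene_order`, with
#'   attribute `window` giving the row index in `sig` of the contributing
#'   window (NA where the profile is 0).
#' @export
build_profile <- function(sig, gene_order) {
  n <- nrow(gene_order)
  value <- numeric(n)
  best_abs <- numeric(n)
  best_size <- rep(Inf, n)
  win_id <- rep(NA_integer_, n)
  offsets <- c(0L, cumsum(table(factor(gene_order$chromosome,
                                       levels = unique(gene_order$chromosome)))))
  names(offsets) <- c(unique(gene_order$chromosome), "_end")
  if (!is.null(sig) && nrow(sig) > 0) {
    for (i in seq_len(nrow(sig))) {
      off <- offsets[[sig$chromosome[i]]]
      idx <- (off + sig$start_index[i] + 1L):(off + sig$end_index[i])
      m <- sig$median[i]
      upd <- (abs(m) > best_abs[idx]) |
        (abs(m) == best_abs[idx] & sig$size[i] < best_size[idx] &
           best_abs[idx] > 0)
      j <- idx[upd]
      value[j] <- m
      best_abs[j] <- abs(m)
      best_size[j] <- sig$size[i]
      win_id[j] <- i
    }
  }
  attr(value, "window") <- win_id
  value
}

#' Convert a profile log2 value to an absolute copy number
#'
#' The profile is a log2 ratio against a diploid control, so the implied
#' copy number is `2 * 2^value`: 0 maps to 2 copies, 1 to 4, -1 to 1.
#'
#' @param profile_value Numeric log2 profile value(s).
#' @return Copy-number estimate(s).
#' @export
profile_to_copy_number <- function(profile_value) {
  2 * 2^profile_value
}

#' Correlation of the aberration profile with copy-number change
#'
#' @param profile_value Per-gene profile log2 values.
#' @param copy_log2 Per-gene copy log2 ratios at the same positions.
#' @return Pearson correlation; NA with a warning when either side has
#'   zero variance (e.g. an all-zero profile).
#' @export
profiled_correlation <- function(profile_value, copy_log2) {
  stopifnot(length(profile_value) == length(copy_log2))
  if (stats::sd(profile_value) == 0 || stats::sd(copy_log2) == 0) {
    warning("profiled correlation undefined: zero variance")
    return(NA_real_)
  }
  stats::cor(profile_value, copy_log2)
}

#' Genome profiling: call amplifications and deletions from protein ratios
#'
#' The full profiling algorithm. Per chromosome, position-ordered protein
#' log2 ratios (median-centered across the genome by default) are scanned
#' with windows from 3 genes up to the whole chromosome in sqrt(2) size
#' steps; each window mean is tested against zero with a one-sample
#' t-test; p-values are converted to posterior error probabilities with a
#' window-size-stratified Bayes-rule histogram against 10 permuted
#' genomes; windows passing a permutation-estimated FDR form the
#' significant set; and the per-gene profile takes, at each position, the
#' significant window median deviating most from zero.
#'
#' @param track Data frame with gene, chromosome, position, log2_ratio.
#' @param fdr Window-level false discovery rate (default 0.02).
#' @param n_permutations Number of randomized genomes (default 10).
#' @param seed Integer seed for the permutations.
#' @param center Median-center the track before scanning (default TRUE).
#' @param n_bins log10-p bins per window-size stratum of the PEP
#'   histograms.
#' @return An object of class `"aberration_profile"`: list with `profile`
#'   (gene, chromosome, position, log2_ratio, profile_value,
#'   copy_number_estimate, window_id), `windows` (all observed windows
#'   with pep and significance), `cutoff`, `fdr`, `n_permutations`.
#' @export
genome_profile <- function(track, fdr = 0.02, n_permutations = 10,
                           seed = 1L, center = TRUE, n_bins = 20) {
  stopifnot(all(c("gene", "chromosome", "position", "log2_ratio") %in%
                  names(track)))
  track <- track[order(factor(track$chromosome,
                              levels = unique(track$chromosome)),
                       track$position), , drop = FALSE]
  x <- track$log2_ratio
  if (center) x <- x - stats::median(x)
  chroms <- unique(track$chromosome)
  chrom_x <- split(x, factor(track$chromosome, levels = chroms))
  short <- vapply(chrom_x, length, integer(1)) < 3
  if (any(short)) {
    warning("chromosome(s) with fewer than 3 genes skipped: ",
            paste(chroms[short], collapse = ", "))
  }
  use <- chroms[!short]

  scan_genome <- function(values_by_chrom, medians) {
    out <- lapply(use, function(ch) {
      w <- scan_chromosome(values_by_chrom[[ch]], medians = medians)
      w$chromosome <- ch
      w
    })
    do.call(rbind, out)
  }
  obs <- scan_genome(chrom_x, medians = TRUE)

  set.seed(seed)
  null_p <- lapply(seq_len(n_permutations), function(k) {
    xp <- randomize_genome(x)
    xp_by <- split(xp, factor(track$chromosome, levels = chroms))
    scan_genome(xp_by, medians = FALSE)$p_value
  })

  pep <- pep_transform(obs, null_p, n_bins = n_bins)
  obs$pep <- pep$pep_obs
  thr <- significance_threshold(pep$pep_obs, pep$pep_null, fdr = fdr)
  obs$significant <- thr$significant

  keep <- track$chromosome %in% use
  gene_order <- track[keep, c("gene", "chromosome", "position")]
  sig <- obs[obs$significant, , drop = FALSE]
  prof_val <- build_profile(sig, gene_order)
  profile <- data.frame(
    gene_order,
    log2_ratio = x[keep],
    profile_value = as.numeric(prof_val),
    copy_number_estimate = profile_to_copy_number(as.numeric(prof_val)),
    window_id = attr(prof_val, "window"),
    stringsAsFactors = FALSE
  )
  structure(list(profile = profile, windows = obs, cutoff = thr$cutoff,
                 fdr = fdr, n_permutations = n_permutations, seed = seed),
            class = "aberration_profile")
}

#' @export
print.aberration_profile <- function(x, ...) {
  nz <- sum(x$profile$profile_value != 0)
  cat("Aberration profile over", nrow(x$profile), "genes on",
      length(unique(x$profile$chromosome)), "chromosomes\n")
  cat(sprintf("  %d/%d windows significant (PEP cutoff %.3g, FDR %.2g)\n",
              sum(x$windows$significant), nrow(x$windows),
              x$cutoff, x$fdr))
  cat(sprintf("  %d genes (%.1f%%) in non-zero profile\n", nz,
              100 * nz / nrow(x$profile)))
  invisible(x)
}

#' Merge an aberration profile into contiguous called segments
#'
#' Maximal runs of same-sign non-zero profile values become segments,
#' labelled amp/del by sign.
#'
#' @param profile The `profile` data frame of an `aberration_profile` (or
#'   the object itself).
#' @return Data frame: chromosome, start_index, end_index (0-based
#'   half-open gene indices within chromosome), start_position,
#'   end_position, n_genes, call ("amp"/"del"), median_value (median
#'   profile value over the run).
#' @export
profile_segments <- function(profile) {
  if (inherits(profile, "aberration_profile")) profile <- profile$profile
  out <- list()
  for (ch in unique(profile$chromosome)) {
    p <- profile[profile$chromosome == ch, , drop = FALSE]
    sgn <- sign(p$profile_value)
    r <- rle(sgn)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != 0
    if (!any(keep)) next
    out[[ch]] <- data.frame(
      chromosome = ch,
      start_index = starts[keep] - 1L,
      end_index = ends[keep],
      start_position = p$position[starts[keep]],
      end_position = p$position[ends[keep]],
      n_genes = r$lengths[keep],
      call = ifelse(r$values[keep] > 0, "amp", "del"),
      median_value = vapply(which(keep), function(i) {
        stats::median(p$profile_value[starts[i]:ends[i]])
      }, numeric(1)),
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) {
    return(data.frame(chromosome = character(0), start_index = integer(0),
                      end_index = integer(0), start_position = integer(0),
                      end_position = integer(0), n_genes = integer(0),
                      call = character(0), median_value = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write called segments as a BED file
#'
#' 0-based half-open genomic intervals, name amp/del, score
#' `min(1000, round(|median| * 1000))`.
#'
#' @param segments Output of [profile_segments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  bed <- data.frame(
    chrom = segments$chromosome,
    start = segments$start_position - 1L,
    end = segments$end_position,
    name = segments$call,
    score = pmin(1000L, as.integer(round(abs(segments$median_value) * 1000)))
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
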