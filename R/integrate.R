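#' SILAC ratio-of-ratios: relative protein level on the log2 scale
#'
#' Two samples measured against a common heavy-labeled internal standard
#' are compared by dividing their ratios, canceling the standard:
#' `log2((tumor/std) / (control/std)) = log2(tumor/control)`.
#' Non-positive ratios cannot arise from valid SILAC quantification; such
#' records are rejected (NA) with a warning.
#'
#' @param tumor_vs_std,control_vs_std Positive numeric ratios (vectorized).
#' @return Numeric log2 relative protein level; NA where an input was
#'   non-positive or missing.
#' @export
ratio_of_ratios <- function(tumor_vs_std, control_vs_std) {
  bad <- !is.finite(tumor_vs_std) | !is.finite(control_vs_std) |
    tumor_vs_std <= 0 | control_vs_std <= 0
  if (any(bad)) {
    warning(sum(bad), " record(s) rejected: non-positive or missing ratio")
  }
  out <- rep(NA_real_, length(bad))
  out[!bad] <- log2(tumor_vs_std[!bad] / control_vs_std[!bad])
  out
}

#' Filter protein records by quantification events
#'
#' Keeps only records supported by at least `min_events` quantification
#' events in their experiment, the standard reliability filter for
#' SILAC protein ratios.
#'
#' @param records Data frame with an `n_events` column.
#' @param min_events Minimum events required (default 2).
#' @return The filtered data frame; the number removed is messaged.
#' @export
filter_quantified <- function(records, min_events = 2) {
  keep <- records$n_events >= min_events
  removed <- sum(!keep)
  if (removed > 0) {
    message(removed, " protein record(s) removed (fewer than ",
            min_events, " quantification events)")
  }
  records[keep, , drop = FALSE]
}

#' Collapse replicate protein measurements to one value per gene
#'
#' Replicates are combined by the median of their log2 ratios (robust to a
#' single outlier replicate among a triplicate); even counts use the mean
#' of the two middle values.
#'
#' @param records Data frame with gene, chromosome, position, log2_ratio
#'   (one row per gene x replicate).
#' @return Data frame with one row per gene: gene, chromosome, position,
#'   log2_ratio.
#' @export
aggregate_replicates <- function(records) {
  stopifnot(all(c("gene", "log2_ratio") %in% names(records)))
  med <- tapply(records$log2_ratio, records$gene, stats::median)
  first <- records[!duplicated(records$gene), , drop = FALSE]
  first <- first[order(first$gene), , drop = FALSE]
  out <- data.frame(
    gene = names(med),
    chromosome = first$chromosome[match(names(med), first$gene)],
    position = first$position[match(names(med), first$gene)],
    log2_ratio = as.numeric(med),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Gene-level copy number from probe smooth signals
#'
#' A gene's copy number is the median of the smooth signals of the probes
#' annotated to it; even probe counts use the mean of the two middle
#' values.
#'
#' @param signals Numeric vector of smooth signals for one gene's probes.
#' @return The median smooth signal.
#' @export
gene_copy_from_probes <- function(signals) {
  stopifnot(length(signals) >= 1)
  stats::median(signals)
}

#' Summarize a probe table to one copy number per gene
#'
#' @param probes Data frame with chromosome, position, gene, smooth_signal.
#' @return Data frame with gene, chromosome, position (first probe
#'   position), copy_number. Genes without probes are simply absent.
#' @export
gene_copy_table <- function(probes) {
  stopifnot(all(c("gene", "smooth_signal") %in% names(probes)))
  med <- tapply(probes$smooth_signal, probes$gene, stats::median)
  o <- order(probes$gene, probes$position)
  first <- probes[o, ][!duplicated(probes$gene[o]), , drop = FALSE]
  out <- data.frame(
    gene = names(med),
    chromosome = first$chromosome[match(names(med), first$gene)],
    position = first$position[match(names(med), first$gene)],
    copy_number = as.numeric(med),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$chromosome, out$position), ]
}

#' Normalize tumor copy numbers to the diploid control
#'
#' @param tumor_copy,control_copy Numeric copy numbers (smooth-signal
#'   units). Both are floored at `eps` so the log2 ratio stays finite for
#'   fully deleted loci.
#' @param eps Flooring constant in smooth-signal units.
#' @return log2(tumor/control) per gene.
#' @export
normalize_to_control <- function(tumor_copy, control_copy, eps = 0.1) {
  stopifnot(eps > 0)
  flagged <- sum(control_copy <= 0)
  if (flagged > 0) {
    warning(flagged, " gene(s) with non-positive control copy floored at ",
            eps)
  }
  log2(pmax(tumor_copy, eps) / pmax(control_copy, eps))
}

#' Match protein and gene copy-number records by gene name
#'
#' Inner join on the gene name. Duplicate gene names on the protein side
#' (several protein groups mapping to one gene) are resolved by keeping the
#' record with the most quantification events, ties broken by smallest
#' position; duplicates on the copy side keep the first by position. Both
#' resolutions and the unmatched counts are reported.
#'
#' @param proteins Data frame with gene, chromosome, position, protein_log2
#'   and optionally n_events.
#' @param gene_copies Data frame with gene, copy_log2.
#' @return Matched data frame: gene, chromosome, position, protein_log2,
#'   copy_log2, ordered by chromosome and position.
#' @export
match_by_gene <- function(proteins, gene_copies) {
  if (anyDuplicated(proteins$gene)) {
    warning("duplicate protein gene name(s); keeping the record with most ",
            "quantification events (ties: smallest position)")
    ev <- if ("n_events" %in% names(proteins)) proteins$n_events else
      rep(1L, nrow(proteins))
    o <- order(proteins$gene, -ev, proteins$position)
    proteins <- proteins[o, ][!duplicated(proteins$gene[o]), , drop = FALSE]
  }
  if (anyDuplicated(gene_copies$gene)) {
    warning("duplicate copy-number gene name(s); keeping first by position")
    o <- order(gene_copies$gene, gene_copies$position)
    gene_copies <- gene_copies[o, ][!duplicated(gene_copies$gene[o]), ,
                                    drop = FALSE]
  }
  m <- merge(proteins[, c("gene", "chromosome", "position", "protein_log2")],
             gene_copies[, c("gene", "copy_log2")], by = "gene")
  n_un_p <- nrow(proteins) - nrow(m)
  n_un_c <- nrow(gene_copies) - nrow(m)
  message("matched ", nrow(m), " genes (", n_un_p,
          " proteins and ", n_un_c, " copy-number genes unmatched)")
  m <- m[order(m$chromosome, m$position), ]
  rownames(m) <- NULL
  m
}

#' Correlation between copy-number change and protein change
#'
#' Pearson correlation of per-gene copy log2 ratios against protein log2
#' ratios, and its square as "percent of protein-level change explained by
#' copy-number change".
#'
#' @param matched Matched gene table with protein_log2 and copy_log2.
#' @return List with `r` and `r2_percent`; both NA (with a warning) when
#'   fewer than 3 genes or a degenerate variance makes the correlation
#'   undefined.
#' @export
correlation_and_r2 <- function(matched) {
  x <- matched$copy_log2
  y <- matched$protein_log2
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("correlation undefined: fewer than 3 genes or zero variance")
    return(list(r = NA_real_, r2_percent = NA_real_))
  }
  r <- stats::cor(x, y)
  list(r = r, r2_percent = 100 * r^2)
}

#' Check that the control sample is diploid
#'
#' Histogram mode of the control smooth-signal density; for a diploid
#' control it must sit at 2. Probes on an excluded chromosome (e.g. a Y
#' chromosome absent from a female cell line, which otherwise adds a
#' spurious peak at 0) are dropped first.
#'
#' @param control_probes Probe table with smooth_signal and chromosome.
#' @param exclude_chromosome Optional chromosome name(s) to drop.
#' @param binwidth Histogram bin width in smooth-signal units.
#' @return The histogram mode (midpoint of the fullest bin); warns when it
#'   falls outside [1.8, 2.2].
#' @export
control_diploidy_check <- function(control_probes, exclude_chromosome = NULL,
                                   binwidth = 0.05) {
  x <- control_probes$smooth_signal
  if (!is.null(exclude_chromosome)) {
    x <- x[!control_probes$chromosome %in% exclude_chromosome]
  }
  stopifnot(length(x) >= 100)
  breaks <- seq(floor(min(x) / binwidth) * binwidth,
                ceiling(max(x) / binwidth) * binwidth + binwidth, by = binwidth)
  h <- hist(x, breaks = breaks, plot = FALSE)
  mode <- h$mids[which.max(h$counts)]
  if (mode < 1.8 || mode > 2.2) {
    warning("control smooth-signal mode ", round(mode, 3),
            " outside [1.8, 2.2]; control may not be diploid")
  }
  mode
}

#' Build the matched per-gene dataset from raw tables
#'
#' Full integration pipeline: ratio-of-ratios per protein record, the
#' min-events filter, replicate aggregation by median, per-gene median
#' probe summarization of tumor and control copy signals, normalization to
#' the control, the gene-name join, and (by default) median-centering of
#' the protein log2 ratios.
#'
#' @param proteins Protein table (gene, chromosome, position,
#'   ratio_tumor_vs_std, ratio_control_vs_std, n_events, replicate).
#' @param tumor_probes,control_probes Probe tables (chromosome, position,
#'   gene, smooth_signal).
#' @param min_events Quantification-event filter threshold.
#' @param center Median-center protein log2 ratios after aggregation.
#' @param eps Flooring constant for [normalize_to_control()].
#' @return Matched gene table: gene, chromosome, position, protein_log2,
#'   copy_log2, copy_number.
#' @export
integrate_datasets <- function(proteins, tumor_probes, control_probes,
                               min_events = 2, center = TRUE, eps = 0.1) {
  proteins$log2_ratio <- ratio_of_ratios(proteins$ratio_tumor_vs_std,
                                         proteins$ratio_control_vs_std)
  proteins <- proteins[!is.na(proteins$log2_ratio), , drop = FALSE]
  proteins <- filter_quantified(proteins, min_events)
  prot <- aggregate_replicates(proteins)
  names(prot)[names(prot) == "log2_ratio"] <- "protein_log2"
  if (center) prot$protein_log2 <- prot$protein_log2 -
      stats::median(prot$protein_log2)

  tum <- gene_copy_table(tumor_probes)
  ctl <- gene_copy_table(control_probes)
  copies <- merge(tum, ctl[, c("gene", "copy_number")], by = "gene",
                  suffixes = c("", "_control"))
  copies$copy_log2 <- normalize_to_control(copies$copy_number,
                                           copies$copy_number_control,
                                           eps = eps)
  m <- match_by_gene(prot, copies[, c("gene", "position", "copy_log2")])
  m$copy_number <- copies$copy_number[match(m$gene, copies$gene)]
  m
}
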