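#' Zoom in on an amplicon region
#'
#' Lists every matched gene inside a genomic region with linear
#' fold-changes (2^log2) in both dimensions and a concordance flag
#' (same-signed copy and protein change). Genes whose protein was not
#' quantified get NA protein columns, so dosage-discordant passengers
#' (amplified but not overexpressed) are visible.
#'
#' @param matched Matched gene table; may contain NA protein_log2 for
#'   copy-only genes.
#' @param chromosome Chromosome name.
#' @param start,end Region bounds in base pairs (inclusive).
#' @return Data frame ordered by position: gene, position, copy_fold,
#'   protein_fold, copy_log2, protein_log2, concordant.
#' @export
amplicon_zoom <- function(matched, chromosome, start, end) {
  stopifnot(start <= end)
  sel <- matched$chromosome == chromosome &
    matched$position >= start & matched$position <= end
  v <- matched[sel, , drop = FALSE]
  if (nrow(v) == 0) {
    warning("no genes in region ", chromosome, ":", start, "-", end)
  }
  out <- data.frame(
    gene = v$gene, position = v$position,
    copy_fold = 2^v$copy_log2,
    protein_fold = 2^v$protein_log2,
    copy_log2 = v$copy_log2, protein_log2 = v$protein_log2,
    concordant = sign(v$copy_log2) == sign(v$protein_log2),
    stringsAsFactors = FALSE
  )
  out[order(out$position), ]
}

#' Intersect the matched dataset with a cancer gene census
#'
#' Census genes whose copy number changed by at least `copy_threshold`
#' (|log2|), flagged concordant when the protein change is same-signed and
#' at least `protein_threshold` — candidate driver genes whose genomic
#' change is propagated to the proteome.
#'
#' @param matched Matched gene table.
#' @param census Data frame with gene and optionally census_role.
#' @param copy_threshold,protein_threshold |log2| thresholds (default
#'   0.32, about 1.25-fold).
#' @return Data frame: gene, census_role, copy_log2, protein_log2,
#'   concordant; ordered by |copy_log2| descending.
#' @export
census_intersect <- function(matched, census, copy_threshold = 0.32,
                             protein_threshold = 0.32) {
  stopifnot(nrow(census) >= 1, "gene" %in% names(census))
  if (!"census_role" %in% names(census)) census$census_role <- ""
  m <- merge(matched, census[, c("gene", "census_role")], by = "gene")
  m <- m[abs(m$copy_log2) >= copy_threshold, , drop = FALSE]
  m$concordant <- sign(m$protein_log2) == sign(m$copy_log2) &
    abs(m$protein_log2) >= protein_threshold
  m <- m[order(-abs(m$copy_log2)),
         c("gene", "census_role", "copy_log2", "protein_log2", "concordant")]
  rownames(m) <- NULL
  m
}

#' Candidate gene lists by copy-change and protein-change sign
#'
#' Partitions genes passing the copy threshold into four lists by the sign
#' of the copy change crossed with the sign of the protein change:
#' amplified-up (dosage propagated), amplified-down (buffered or
#' counter-regulated), deleted-down, deleted-up. The copy criterion can
#' come either from the per-gene copy log2 ratio or from membership in a
#' called profile segment.
#'
#' @param matched Matched gene table.
#' @param profile Optional `aberration_profile` (or its `profile` data
#'   frame); when given, the copy change of a gene is taken from its
#'   profile value instead of copy_log2.
#' @param copy_threshold,protein_threshold |log2| thresholds (default
#'   0.32).
#' @return Named list of four data frames (amplified_up, amplified_down,
#'   deleted_down, deleted_up), each sorted by |protein_log2| descending.
#' @export
candidate_lists <- function(matched, profile = NULL, copy_threshold = 0.32,
                            protein_threshold = 0.32) {
  copy_change <- matched$copy_log2
  if (!is.null(profile)) {
    if (inherits(profile, "aberration_profile")) profile <- profile$profile
    copy_change <- profile$profile_value[match(matched$gene, profile$gene)]
    copy_change[is.na(copy_change)] <- 0
  }
  pass_copy <- abs(copy_change) >= copy_threshold
  pass_prot <- abs(matched$protein_log2) >= protein_threshold
  pick <- function(cs, ps) {
    sel <- pass_copy & pass_prot & sign(copy_change) == cs &
      sign(matched$protein_log2) == ps
    out <- matched[sel, , drop = FALSE]
    out <- out[order(-abs(out$protein_log2)), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  list(amplified_up = pick(1, 1), amplified_down = pick(1, -1),
       deleted_down = pick(-1, -1), deleted_up = pick(-1, 1))
}
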