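#' Per-gene ranks in the copy and protein dimensions
#'
#' Ascending ranks 1..n in each of the two numerical dimensions (copy log2
#' ratio, protein log2 ratio); ties receive average ranks.
#'
#' @param matched Matched gene table with copy_log2 and protein_log2.
#' @return List with `genome` and `proteome` rank vectors (aligned with
#'   the rows of `matched`) and `n`.
#' @export
rank_dimensions <- function(matched) {
  stopifnot(nrow(matched) >= 2,
            all(is.finite(matched$copy_log2)),
            all(is.finite(matched$protein_log2)))
  tie_term <- function(r) {
    t <- tabulate(match(r, unique(r)))
    sum(t^3 - t)
  }
  g <- rank(matched$copy_log2, ties.method = "average")
  p <- rank(matched$protein_log2, ties.method = "average")
  list(genome = g, proteome = p, n = nrow(matched),
       tie_genome = tie_term(g), tie_proteome = tie_term(p))
}

# Standardized Mann-Whitney z for a member set in one rank dimension, with
# tie correction of the U variance. tie_term = sum(t^3 - t) over tie-group
# sizes t, precomputed once per dimension in rank_dimensions().
.mw_z <- function(ranks, is_member, tie_term = 0) {
  n <- length(ranks)
  m <- sum(is_member)
  U <- sum(ranks[is_member]) - m * (m + 1) / 2
  mu <- m * (n - m) / 2
  v <- m * (n - m) / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (v <= 0) return(0)
  (U - mu) / sqrt(v)
}

#' Two-dimensional Mann-Whitney test for one annotation term
#'
#' Members of the term are compared against the complement in the joint
#' (copy log2, protein log2) rank space: each dimension yields a
#' standardized Mann-Whitney statistic z_d (tie-corrected), and the
#' combined statistic z1^2 + z2^2 is referred to a chi-square distribution
#' with 2 degrees of freedom. The combination is exact for independent
#' dimensions at large n, is rank-based, and reduces to the ordinary
#' two-sided Mann-Whitney test when one dimension is ignored. An optional
#' permutation p-value (membership labels permuted) is available as the
#' exact alternative when the dimensions are correlated.
#'
#' @param is_member Logical vector over the gene universe.
#' @param ranks Output of [rank_dimensions()].
#' @param n_perm 0 for the analytic chi-square p-value; otherwise the
#'   number of label permutations.
#' @return List with `p_value`, `z_genome`, `z_proteome`, `statistic`.
#' @export
mannwhitney_2d <- function(is_member, ranks, n_perm = 0) {
  m <- sum(is_member)
  n <- ranks$n
  stopifnot(m >= 1, m < n, length(is_member) == n)
  tg <- if (is.null(ranks$tie_genome)) 0 else ranks$tie_genome
  tp <- if (is.null(ranks$tie_proteome)) 0 else ranks$tie_proteome
  z1 <- .mw_z(ranks$genome, is_member, tg)
  z2 <- .mw_z(ranks$proteome, is_member, tp)
  stat <- z1^2 + z2^2
  if (n_perm > 0) {
    exceed <- sum(vapply(seq_len(n_perm), function(i) {
      perm <- sample(is_member)
      .mw_z(ranks$genome, perm, tg)^2 +
        .mw_z(ranks$proteome, perm, tp)^2 >= stat
    }, logical(1)))
    p <- (exceed + 1) / (n_perm + 1)
  } else {
    p <- stats::pchisq(stat, df = 2, lower.tail = FALSE)
  }
  list(p_value = p, z_genome = z1, z_proteome = z2, statistic = stat)
}

#' Rescaled mean-rank score of a term in one dimension
#'
#' The average rank of the term's members, affinely rescaled to [-1, 1]:
#' 1 means all members are the largest values in the dimension, 0 means
#' the members' ranks are distributed like the background, -1 means all
#' members are the smallest values. Concretely
#' `(meanRank - (n+1)/2) / ((n - m)/2)`.
#'
#' @param is_member Logical vector over the gene universe.
#' @param ranks_1d Rank vector for one dimension.
#' @return Score in [-1, 1].
#' @export
score_2d <- function(is_member, ranks_1d) {
  n <- length(ranks_1d)
  m <- sum(is_member)
  stopifnot(m >= 1, m < n)
  (mean(ranks_1d[is_member]) - (n + 1) / 2) / ((n - m) / 2)
}

#' Benjamini-Hochberg adjustment and significance call
#'
#' @param p_values Numeric p-values.
#' @param fdr Significance threshold on the adjusted values (default
#'   0.05).
#' @return List with `q_values` (BH step-up adjusted) and `significant`
#'   (logical).
#' @export
bh_adjust <- function(p_values, fdr = 0.05) {
  q <- stats::p.adjust(p_values, method = "BH")
  list(q_values = q, significant = q <= fdr)
}

#' Chromosome pseudo-terms from a matched gene table
#'
#' The chromosome of a gene is treated as an additional annotation: one
#' term per chromosome containing its matched genes.
#'
#' @param matched Matched gene table with gene and chromosome.
#' @return Named list of member gene vectors with a `source` attribute
#'   `"chromosome"`.
#' @export
chromosome_terms <- function(matched) {
  terms <- split(matched$gene, matched$chromosome)
  attr(terms, "source") <- rep("chromosome", length(terms))
  terms
}

#' Two-dimensional annotation distribution analysis
#'
#' Tests every annotation term for a coordinated shift of its members in
#' the joint (copy-number change, protein change) space, scores each
#' significant dimension by the rescaled mean rank, and controls multiple
#' testing with Benjamini-Hochberg at 5% FDR. Chromosome pseudo-terms are
#' appended by default, so arm-level dosage effects appear as shifted
#' chromosome categories in the genome dimension.
#'
#' @param matched Matched gene table (gene, copy_log2, protein_log2).
#' @param terms Named list(s) of member gene vectors; a `source` attribute
#'   labels each term's origin (e.g. "GOBP", "KEGG", "CORUM"). Pass the
#'   result of [read_gmt()] or concatenate several with [c()].
#' @param min_category_size Terms smaller than this (after intersection
#'   with the matched universe), or larger than `n - min_category_size`,
#'   are skipped.
#' @param fdr BH threshold (default 0.05).
#' @param n_perm 0 for analytic p-values, else permutation count per term.
#' @param add_chromosome_terms Append chromosome pseudo-terms.
#' @return Data frame ordered by q_value: term_id, source, n_members,
#'   p_value, q_value, score_genome, score_proteome, significant.
#' @export
run_annotation_analysis <- function(matched, terms, min_category_size = 5,
                                    fdr = 0.05, n_perm = 0,
                                    add_chromosome_terms = TRUE) {
  src <- attr(terms, "source")
  if (is.null(src)) src <- rep("GMT", length(terms))
  terms <- as.list(terms)
  if (add_chromosome_terms) {
    ct <- chromosome_terms(matched)
    src <- c(src, attr(ct, "source"))
    terms <- c(terms, as.list(ct))
  }
  if (length(terms) == 0) {
    warning("no annotation terms retained")
    return(data.frame(term_id = character(0), source = character(0),
                      n_members = integer(0), p_value = numeric(0),
                      q_value = numeric(0), score_genome = numeric(0),
                      score_proteome = numeric(0),
                      significant = logical(0)))
  }
  ranks <- rank_dimensions(matched)
  n <- ranks$n
  rows <- lapply(seq_along(terms), function(i) {
    is_member <- matched$gene %in% terms[[i]]
    m <- sum(is_member)
    if (m < min_category_size || m > n - min_category_size) return(NULL)
    tst <- mannwhitney_2d(is_member, ranks, n_perm = n_perm)
    data.frame(
      term_id = names(terms)[i], source = src[i], n_members = m,
      p_value = tst$p_value,
      score_genome = score_2d(is_member, ranks$genome),
      score_proteome = score_2d(is_member, ranks$proteome),
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    warning("no annotation terms retained after size filtering")
    return(data.frame(term_id = character(0), source = character(0),
                      n_members = integer(0), p_value = numeric(0),
                      q_value = numeric(0), score_genome = numeric(0),
                      score_proteome = numeric(0),
                      significant = logical(0)))
  }
  res <- do.call(rbind, rows)
  adj <- bh_adjust(res$p_value, fdr = fdr)
  res$q_value <- adj$q_values
  res$significant <- adj$significant
  res <- res[order(res$q_value, res$p_value), c(
    "term_id", "source", "n_members", "p_value", "q_value",
    "score_genome", "score_proteome", "significant")]
  rownames(res) <- NULL
  res
}
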