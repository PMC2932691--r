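#' Write a data frame as TSV with an optional comment header
#'
#' @param x Data frame.
#' @param path Output path.
#' @param comments Character vector written as `# `-prefixed header lines
#'   (used to echo the simulation seed into every output for
#'   reproducibility).
#' @return `path`, invisibly.
#' @export
write_tsv_c <- function(x, path, comments = character(0)) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by this package (comment lines ignored)
#'
#' @param path Input path.
#' @param column_map Optional named character vector renaming file columns
#'   to the package's canonical names, e.g.
#'   `c(gene = "Gene names", smooth_signal = "SmoothSignal")` for
#'   MaxQuant-like or Affymetrix-like exports.
#' @return A data frame.
#' @export
read_tsv_c <- function(path, column_map = NULL) {
  x <- utils::read.delim(path, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(x)) stop("column not found: ", src)
      names(x)[names(x) == src] <- canon
    }
  }
  x
}

#' Write annotation terms in GMT format
#'
#' One line per term: `term<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param terms Named list of character vectors of member genes.
#' @param path Output path.
#' @param descriptions Optional character vector of term descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(terms, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(terms))
  lines <- vapply(seq_along(terms), function(i) {
    paste(c(names(terms)[i], descriptions[i], terms[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT annotation file
#'
#' @param path Input path.
#' @param source Source label attached to every term (e.g. "GOBP",
#'   "KEGG", "CORUM").
#' @return Named list of member gene vectors with a `source` attribute.
#' @export
read_gmt <- function(path, source = "GMT") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  terms <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(terms) <- vapply(parts, `[[`, character(1), 1)
  attr(terms, "source") <- rep(source, length(terms))
  terms
}

#' Write a simulated dataset to a directory
#'
#' Emits the protein table, tumor and control probe tables, the truth gene
#' table and the GMT term file, each with the generating seed echoed in a
#' comment header.
#'
#' @param dataset Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed_note <- paste0("seed=", dataset$truth$seed)
  write_tsv_c(dataset$proteins, file.path(dir, "proteins.tsv"), seed_note)
  write_tsv_c(dataset$tumor_probes, file.path(dir, "tumor_probes.tsv"), seed_note)
  write_tsv_c(dataset$control_probes, file.path(dir, "control_probes.tsv"), seed_note)
  write_tsv_c(dataset$truth$genes, file.path(dir, "truth_genes.tsv"), seed_note)
  write_gmt(dataset$terms, file.path(dir, "terms.gmt"))
  invisible(dir)
}
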