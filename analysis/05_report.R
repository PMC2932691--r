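#!/usr/bin/env Rscript
# Stage 5: interpretation tables.
#
# Zooms in on the strongest called amplicon, intersects the matched data
# with a (synthetic) cancer-gene-census list, and writes the four
# candidate lists given by the sign of the copy change crossed with the
# sign of the protein change. Genes amplified but not overexpressed
# (the buffered/discordant class) surface in the amplified_down list.

library(proteocna)

matched <- read_tsv_c("results/matched.tsv")
segs <- read_tsv_c("results/segments.tsv")

# zoom on the strongest focal amplified segment (arm-level calls are
# visualized by the whole profile, not a zoom)
amp <- segs[segs$call == "amp" & segs$n_genes <= 100, ]
if (nrow(amp) == 0) amp <- segs[segs$call == "amp", ]
amp <- amp[order(-abs(amp$median_value)), ]
if (nrow(amp) > 0) {
  top <- amp[1, ]
  zoom <- amplicon_zoom(matched, top$chromosome,
                        top$start_position, top$end_position)
  write_tsv_c(zoom, "results/amplicon_zoom.tsv")
  message(sprintf("strongest amplicon: %s:%d-%d (%d genes, median %.2f log2)",
                  top$chromosome, top$start_position, top$end_position,
                  top$n_genes, top$median_value))
  message(sprintf("  %d/%d genes in the amplicon concordantly overexpressed",
                  sum(zoom$concordant, na.rm = TRUE), nrow(zoom)))
}

# synthetic census list: the most-amplified matched genes plus random
# controls stand in for a curated cancer gene census
set.seed(31)
census <- data.frame(
  gene = c(matched$gene[order(-matched$copy_log2)][1:20],
           sample(matched$gene, 30)),
  census_role = "synthetic census entry"
)
hits <- census_intersect(matched, census)
write_tsv_c(hits, "results/census_hits.tsv")
message(sprintf("census intersection: %d hits, %d concordant",
                nrow(hits), sum(hits$concordant)))

# candidate lists keyed on the measured copy change; in the attenuated
# regime the protein-side profile understates the dosage amplitude, so
# the copy dimension is the cleaner partitioning axis here
cl <- candidate_lists(matched)
for (nm in names(cl)) {
  write_tsv_c(cl[[nm]], file.path("results", paste0("candidates_", nm, ".tsv")))
}
message(sprintf(
  "candidate lists: %d amplified-up, %d amplified-down, %d deleted-down, %d deleted-up",
  nrow(cl$amplified_up), nrow(cl$amplified_down),
  nrow(cl$deleted_down), nrow(cl$deleted_up)))
message("wrote results/amplicon_zoom.tsv, census_hits.tsv, candidates_*.tsv")
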