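#!/usr/bin/env Rscript
# Stage 3 — gene-set over-representation of the DE lists.
#
# Takes the Choice-vs-Standard high-confidence up/down lists from stage 2
# and tests them against a gene-set collection with the hypergeometric
# (Fisher exact) and EASE scores, background = all tested genes, flagging
# terms at raw p < 0.1. The shipped collection is synthetic (random sets
# over the simulated gene ids), so this demonstrates the machinery; point
# `gmt` at a real KEGG/GO GMT export to analyze real lists.

suppressPackageStartupMessages(library(gradexpr))
outdir <- "results/enrichment"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

de <- read.delim("results/de/de_choice_vs_standard.tsv")
gmt <- system.file("extdata", "synthetic_sets.gmt", package = "gradexpr")
coll <- read_gmt(gmt)
background <- de$gene

lists <- list(up = de$gene[de$flag_subset & de$direction == "up"],
              down = de$gene[de$flag_subset & de$direction == "down"])
for (dir in names(lists)) {
  for (mode in c("fisher", "ease")) {
    res <- suppressWarnings(
      enrich(lists[[dir]], coll, background = background, mode = mode))
    write_tsv_table(res, file.path(outdir, sprintf("%s_%s.tsv", dir, mode)))
    cat(sprintf("%-4s list (%3d genes), %-6s: %d/%d terms at p < 0.1\n",
                dir, length(lists[[dir]]), mode,
                sum(res$enriched), nrow(res)))
  }
}
cat("Enrichment tables written to", outdir, "\n")
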