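#!/usr/bin/env Rscript
# Stage 4 — prorejuvenative / progeronic classification and responsiveness.
#
# PR-DEGs: Aged-DEGs whose direction is reversed in the Ahet contrast
# (aged retina pulled back toward young). PG-DEGs: Aged-DEGs recapitulated
# concordantly in the Yhet contrast (young retina pushed toward aged).
# Responsiveness = percentage of Aged-DEGs per cell type in each class.

suppressMessages(library(parabioRescue))

ds <- read_dataset_bundle("results/data")
degs <- read_deg_table("results/degs.tsv")

cts <- sort(unique(degs$cell_type))
cls <- lapply(cts, function(tp) {
  d <- function(cn) degs[degs$cell_type == tp & degs$contrast == cn, ]
  rescue_classification(d("Aged"), d("Ahet"), d("Yhet"), mode = "strict")
})
resp <- responsiveness(cls)
utils::write.table(resp, "results/responsiveness.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat("per-cell-type responsiveness (strict mode):\n")
print(resp, digits = 4)

# agreement with the planted rescued subsets
tg <- ds$truth$genes
for (i in seq_along(cts)) {
  pr <- cls[[i]]$pr_degs$gene
  planted <- tg$gene[tg$cell_type == cts[i] & tg$rescued]
  jac <- length(intersect(pr, planted)) / length(union(pr, planted))
  cat(sprintf("%s: strict-PR vs planted rescued subset Jaccard %.2f\n",
              cts[i], jac))
}

# loose mode for comparison (plain intersections)
loose <- responsiveness(lapply(cts, function(tp) {
  d <- function(cn) degs[degs$cell_type == tp & degs$contrast == cn, ]
  rescue_classification(d("Aged"), d("Ahet"), d("Yhet"), mode = "loose")
}))
cat("\nloose-mode pct_pr for comparison:",
    paste(sprintf("%s=%.1f", loose$cell_type, loose$pct_pr), collapse = ", "),
    "\n")
cat("responsiveness table written to results/responsiveness.tsv\n")
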