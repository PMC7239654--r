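#!/usr/bin/env Rscript

# Step 3: cross-screen comparison. Takes the union of genes significant
# (q < 0.01) in at least one screen, compares them on IGTIOB scores — which,
# unlike the enrichment q-value, do not depend on screen-specific sequencing
# depth — and orders the genes by hierarchical clustering of their IGTIOB
# profiles (Euclidean distance, average linkage). Writes the heat-map table.

suppressPackageStartupMessages(library(gtscreen))

res <- lapply(c("screen1", "screen2"), function(id) {
  tibble::as_tibble(read.table(file.path("results", paste0(id, "_hits.tsv")),
                               header = TRUE, sep = "\t"))
})

cmp <- compare_screens(res, alpha = 0.01)
write_comparison_tsv(cmp, "results/screen_comparison.tsv")

print(cmp)
both <- rowSums(cmp$q_matrix < 0.01) == 2
cat("significant in both screens:",
    paste(cmp$genes[both], collapse = ", "), "\n")
cat("significant in one screen:",
    paste(cmp$genes[!both], collapse = ", "), "\n")
cat("heat-map row order:", paste(cmp$genes, collapse = " > "), "\n")
cat("wrote results/screen_comparison.tsv\n")
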