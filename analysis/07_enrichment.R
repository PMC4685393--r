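#!/usr/bin/env Rscript
# Step 7: gene-set over-representation of the module genes against the
# GMT collection, with the weighted network as the background universe
# and Benjamini-Hochberg selection at adjusted P < 0.25.

library(ssnetgwas)

records <- parse_interactions("results/data/interactions.tsv")
ppi <- filter_edges(records, min_pubs = 2)
scores <- read.delim("results/gene_scores.tsv")
models <- read_gene_models("results/data/genes.tsv")
ann <- annotate_weights(ppi, scores, models)

ev <- read.delim("results/modules_evaluated.tsv")
union_genes <- sort(unique(unlist(module_genes(ev$genes[ev$pass]))))
if (length(union_genes) == 0) {
  cat("no surviving module genes; enrichment skipped\n")
} else {
  collection <- read_gmt("results/data/sets.gmt")
  background <- igraph::V(ann$network)$name[igraph::V(ann$network)$weighted]
  res <- fisher_enrichment(union_genes, collection, background)
  write.table(res, "results/enrichment.tsv", sep = "\t", quote = FALSE,
              row.names = FALSE)
  sel <- select_enriched(res, 0.25)
  cat("tested", nrow(res), "gene sets against a background of",
      length(background), "genes\n")
  print(res[, c("term", "overlap", "set_size", "p", "p_adj")],
        row.names = FALSE)
  cat("selected at BH-adjusted P < 0.25:",
      if (nrow(sel)) paste(sel$term, collapse = ", ") else "none", "\n")
}
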