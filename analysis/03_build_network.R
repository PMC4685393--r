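#!/usr/bin/env Rscript
# Step 3: node-weighted interactome. Interactions supported by fewer than
# two publications are dropped; each remaining gene gets z = qnorm(1 - p)
# as its node weight, except significant MHC genes (sigMHC-genes: inside
# the MHC region with gene P < 0.05), which stay in the network unweighted
# and are excluded as search seeds.

library(ssnetgwas)

records <- parse_interactions("results/data/interactions.tsv")
ppi <- filter_edges(records, min_pubs = 2)
scores <- read.delim("results/gene_scores.tsv")
models <- read_gene_models("results/data/genes.tsv")
ann <- annotate_weights(ppi, scores, models)

write_edge_list(ann$network, "results/network_edges.tsv")
writeLines(ann$sig_mhc_genes, "results/sigmhc_genes.txt")

v <- igraph::V(ann$network)
cat("node-weighted network:", length(v), "nodes,",
    igraph::ecount(ann$network), "edges\n")
cat("weighted genes:", sum(v$weighted), "| sigMHC-genes:",
    length(ann$sig_mhc_genes),
    if (length(ann$sig_mhc_genes))
      paste0("(", paste(ann$sig_mhc_genes, collapse = " "), ")") else "",
    "\n")
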