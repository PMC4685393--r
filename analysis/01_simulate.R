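#!/usr/bin/env Rscript
# Step 1: generate the synthetic study inputs with known ground truth.
# A 1,000-gene scale-free interactome with publication-support edge
# counts, a planted 8-gene disease module (gene P < 1e-3), a mock MHC
# region on chromosome 6, and single tag SNPs carrying each gene's
# association P-value. Files land in results/data/.

library(ssnetgwas)

seed <- 2048L
cfg <- synthetic_config(n_nodes = 1000, attach_edges = 3, planted_size = 8,
                        signal_p_max = 1e-3, n_mhc = 40,
                        pub_count_range = c(1L, 5L), seed = seed)
net <- simulate_network(cfg)
ds <- plant_module(net, cfg$planted_size, cfg$signal_p_max, seed = seed)
paths <- write_fixture(ds, "results/data")

# a small gene-set collection for the enrichment step: the planted module,
# a half-overlapping set, and background noise sets
ids <- igraph::V(net)$name
set.seed(seed)
gmt <- c(
  paste(c("PLANTED", "planted disease module", ds$planted_genes),
        collapse = "\t"),
  paste(c("HALF", "half-overlap set", ds$planted_genes[1:4],
          sample(setdiff(ids, ds$planted_genes), 8)), collapse = "\t"),
  paste(c("NOISE1", "random set", sample(ids, 15)), collapse = "\t"),
  paste(c("NOISE2", "random set", sample(ids, 25)), collapse = "\t"))
writeLines(gmt, "results/data/sets.gmt")

cat("simulated interactome:", igraph::vcount(net), "genes,",
    igraph::ecount(net), "interactions\n")
cat("planted module:", paste(ds$planted_genes, collapse = " "), "\n")
cat("MHC-region genes:", sum(igraph::V(net)$in_mhc), "\n")
cat("files:", paste(basename(c(paths, "sets.gmt")), collapse = ", "),
    "-> results/data/\n")
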