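# Shared fixtures and independent oracles, all built in code.

# Toy interaction file from hand-countable records: publication counts
# 1, 2, 3, 1, 2 across five canonical pairs.
write_toy_interactions <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c("A\tB\tPUBS",
               "n1\tn2\tpmid:1",
               "n2\tn3\tpmid:1|pmid:2",
               "n3\tn4\tpmid:1|pmid:2|pmid:3",
               "n4\tn5\tpmid:9",
               "n5\tn1\tpmid:4|pmid:5"), path)
  path
}

# Small weighted graph: named igraph with z directly attached (weighted
# nodes are those with non-NA z).
make_weighted_graph <- function(edges, z) {
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  igraph::V(g)$z <- unname(z[igraph::V(g)$name])
  g
}

# Star graph: center plus `good` leaves at z_good and `bad` leaves at z_bad.
make_star_graph <- function(z_center, z_good, n_good, z_bad = -5,
                            n_bad = 3) {
  leaves <- c(sprintf("good%d", seq_len(n_good)),
              if (n_bad > 0) sprintf("bad%d", seq_len(n_bad)))
  edges <- as.vector(rbind("center", leaves))
  z <- c(center = z_center,
         stats::setNames(rep(z_good, n_good),
                         sprintf("good%d", seq_len(n_good))),
         if (n_bad > 0) stats::setNames(rep(z_bad, n_bad),
                                        sprintf("bad%d", seq_len(n_bad))))
  make_weighted_graph(edges, z)
}

# Exhaustive oracle: maximum module score over every connected subgraph
# containing `seed`, by enumerating all vertex subsets (graphs <= 12 nodes).
oracle_best_score <- function(graph, seed) {
  n <- igraph::vcount(graph)
  stopifnot(n <= 12)
  ids <- igraph::V(graph)$name
  z <- igraph::V(graph)$z
  s <- match(seed, ids)
  adj <- lapply(igraph::adjacent_vertices(graph, igraph::V(graph)),
                as.integer)
  others <- setdiff(which(!is.na(z)), s)
  best <- z[s]
  for (mask in 0:(2^length(others) - 1)) {
    subset <- c(s, others[bitwAnd(mask, 2^(seq_along(others) - 1)) > 0])
    # BFS connectivity within the subset
    seen <- s
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- setdiff(intersect(unique(unlist(adj[frontier])), subset), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    if (length(seen) == length(subset)) {
      sc <- sum(z[subset]) / sqrt(length(subset))
      if (sc > best) best <- sc
    }
  }
  best
}

# Random connected graph with N(0,1) node weights, for oracle comparisons.
random_weighted_graph <- function(n, p = 0.35, seed = 1) {
  set.seed(seed)
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  igraph::V(g)$z <- stats::rnorm(n)
  g
}

# Annotated synthetic network with planted signal, bypassing the SNP stage:
# gene P-values come straight from plant_module.
make_annotated_dataset <- function(n_nodes = 500, attach_edges = 3,
                                   planted_size = 8, signal_p_max = 0.001,
                                   n_mhc = 0, seed = 1) {
  cfg <- synthetic_config(n_nodes = n_nodes, attach_edges = attach_edges,
                          planted_size = planted_size,
                          signal_p_max = signal_p_max, n_mhc = n_mhc,
                          seed = seed)
  net <- simulate_network(cfg)
  ds <- plant_module(net, planted_size, signal_p_max, seed = seed)
  scores <- data.frame(gene_id = names(ds$gene_pvalues),
                       p_value = unname(ds$gene_pvalues),
                       stringsAsFactors = FALSE)
  gene_models <- NULL
  if (n_mhc > 0) {
    dir <- tempfile()
    paths <- write_fixture(ds, dir)
    gene_models <- read_gene_models(paths[["genes"]])
  }
  ann <- suppressMessages(annotate_weights(net, scores, gene_models))
  list(dataset = ds, annotated = ann)
}
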