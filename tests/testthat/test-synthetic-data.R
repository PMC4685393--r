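test_that("simulated network has the requested size and is reproducible", {
  cfg <- synthetic_config(n_nodes = 100, attach_edges = 2, seed = 7)
  g1 <- simulate_network(cfg)
  g2 <- simulate_network(cfg)
  expect_equal(igraph::vcount(g1), 100)
  expect_true(igraph::is_connected(g1))
  expect_false(igraph::any_loop(g1))
  expect_false(igraph::any_multiple(g1))
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
  expect_identical(igraph::E(g1)$n_pubs, igraph::E(g2)$n_pubs)
})

test_that("preferential attachment yields hubs", {
  g <- simulate_network(synthetic_config(n_nodes = 500, attach_edges = 3,
                                         seed = 1))
  deg <- igraph::degree(g)
  expect_gt(max(deg), stats::median(deg) * 5)
})

test_that("invalid configuration errors name the offending field", {
  expect_error(synthetic_config(n_nodes = 3, attach_edges = 5), "n_nodes")
  expect_error(synthetic_config(signal_p_max = 0), "signal_p_max")
  expect_error(synthetic_config(planted_size = 1), "planted_size")
  expect_error(synthetic_config(pub_count_range = c(3, 1)),
               "pub_count_range")
})

test_that("edge publication counts respect the configured range and the
           low-support fraction", {
  cfg <- synthetic_config(n_nodes = 200, attach_edges = 2,
                          pub_count_range = c(2L, 5L),
                          low_support_frac = 0.3, seed = 5)
  g <- simulate_network(cfg)
  pubs <- igraph::E(g)$n_pubs
  expect_true(all(pubs >= 1 & pubs <= 5))
  expect_gte(mean(pubs == 1), 0.25)
})

test_that("planted module is connected with bounded P-values", {
  res <- make_annotated_dataset(n_nodes = 300, planted_size = 8,
                                signal_p_max = 0.001, seed = 3)
  ds <- res$dataset
  expect_length(ds$planted_genes, 8)
  expect_true(all(ds$gene_pvalues[ds$planted_genes] < 0.001))
  sub <- igraph::induced_subgraph(
    ds$network, match(ds$planted_genes, igraph::V(ds$network)$name))
  expect_true(igraph::is_connected(sub))
  expect_identical(sort(names(which(ds$truth_labels == "signal"))),
                   ds$planted_genes)
})

test_that("planting two genes on a path graph picks an adjacent pair", {
  g <- igraph::make_ring(10, circular = FALSE)
  igraph::V(g)$name <- sprintf("p%02d", 1:10)
  ds <- plant_module(g, 2, 0.001, seed = 4)
  idx <- match(ds$planted_genes, igraph::V(g)$name)
  expect_true(igraph::are_adjacent(g, idx[1], idx[2]))
})

test_that("planting a module larger than the network errors", {
  g <- igraph::make_ring(5)
  igraph::V(g)$name <- letters[1:5]
  expect_error(plant_module(g, 6, 0.5, seed = 1), "exceeds")
})

test_that("background P-values are uniform", {
  res <- make_annotated_dataset(n_nodes = 2000, attach_edges = 2,
                                planted_size = 8, seed = 9)
  ds <- res$dataset
  bg <- ds$gene_pvalues[ds$truth_labels == "background"]
  expect_gt(stats::ks.test(bg, "punif")$p.value, 0.01)
})

test_that("SNP block honours the AR(1) correlation target", {
  blk <- simulate_snp_block(10, rho = 0, n_samples = 5000, seed = 2)
  r <- stats::cor(t(blk$genotypes))
  expect_lt(mean(abs(r[upper.tri(r)])), 0.05)
  blk8 <- simulate_snp_block(6, rho = 0.8, n_samples = 5000, seed = 2)
  r8 <- stats::cor(t(blk8$genotypes))
  lag1 <- r8[cbind(1:5, 2:6)]
  expect_lt(mean(abs(lag1 - 0.8)), 0.03)
})

test_that("null SNP P-values are calibrated and rho is validated", {
  expect_error(simulate_snp_block(5, rho = 1, n_samples = 100), "rho")
  blk <- simulate_snp_block(1000, rho = 0, n_samples = 2000, effect = 0,
                            seed = 6)
  expect_true(mean(blk$p_values < 0.05) >= 0.03 &&
                mean(blk$p_values < 0.05) <= 0.07)
})

test_that("fixtures round-trip through the pipeline readers", {
  res <- make_annotated_dataset(n_nodes = 120, attach_edges = 2,
                                planted_size = 5, n_mhc = 10, seed = 8)
  ds <- res$dataset
  dir <- tempfile()
  paths <- write_fixture(ds, dir)
  assoc <- read_associations(paths[["association"]])
  got <- stats::setNames(assoc$p_value, sub("^tag_", "", assoc$snp_id))
  expect_equal(got[names(ds$gene_pvalues)], ds$gene_pvalues,
               tolerance = 1e-12)
  n_lines <- length(readLines(paths[["interactions"]]))
  expect_equal(n_lines, igraph::ecount(ds$network) + 1)
  truth <- utils::read.delim(paths[["truth"]])
  expect_equal(sum(truth$label == "signal"), 5)
  # byte-identical rewrite under the same seed chain
  dir2 <- tempfile()
  write_fixture(ds, dir2)
  for (nm in names(paths))
    expect_identical(readLines(paths[[nm]]),
                     readLines(file.path(dir2, basename(paths[[nm]]))))
})
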