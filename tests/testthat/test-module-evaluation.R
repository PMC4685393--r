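test_that("empirical null recovers standard normal parameters", {
  set.seed(101)
  nd <- fit_empirical_null(stats::rnorm(10000))
  expect_gt(nd$mu, -0.05); expect_lt(nd$mu, 0.05)
  expect_gt(nd$sigma, 0.95); expect_lt(nd$sigma, 1.05)
})

test_that("median centering removes location, central fit recovers scale", {
  set.seed(102)
  nd <- fit_empirical_null(stats::rnorm(10000, mean = 3, sd = 2))
  expect_equal(nd$center, 3, tolerance = 0.1)
  expect_lt(abs(nd$mu), 0.1)
  expect_gt(nd$sigma, 1.9); expect_lt(nd$sigma, 2.1)
})

test_that("central matching resists right contamination", {
  set.seed(103)
  scores <- c(stats::rnorm(9500), stats::rnorm(500, mean = 8, sd = 0.5))
  nd <- fit_empirical_null(scores)
  expect_gt(nd$sigma, 0.9); expect_lt(nd$sigma, 1.15)
})

test_that("degenerate scores are rejected and few scores warn", {
  expect_error(fit_empirical_null(rep(2, 100)), "degenerate")
  expect_warning(fit_empirical_null(stats::rnorm(30)), "only 30")
})

test_that("stage-1 P-values are the upper-tail normal probabilities", {
  nd <- structure(list(mu = 0, sigma = 1, method = "central_matching",
                       n_scores = 100, center = 0),
                  class = "null_distribution")
  expect_equal(normal_stage_pvalues(0, nd), 0.5)
  expect_equal(normal_stage_pvalues(1.6449, nd), 0.05, tolerance = 1e-4)
  s <- seq(-2, 4, by = 0.5)
  expect_true(all(diff(normal_stage_pvalues(s, nd)) < 0))
})

test_that("degree quartile bins match the hand computation", {
  # realizable sequence 1,2,3,4,4,5,6,7,8: quartiles (type 7) are 3, 4, 6;
  # ties to the lower bin gives 1,2,3 -> bin1; 4,4 -> bin2; 5,6 -> bin3;
  # 7,8 -> bin4
  g <- igraph::realize_degseq(c(1, 2, 3, 4, 4, 5, 6, 7, 8))
  igraph::V(g)$name <- sprintf("n%d", 1:9)
  bins <- assign_degree_bins(g)
  deg <- igraph::degree(g)
  expect_identical(unname(bins$assignment[order(deg, seq_along(deg))]),
                   c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_equal(sum(table(bins$assignment)), igraph::vcount(g))
})

test_that("equal degrees collapse into the lowest bin", {
  g <- igraph::make_ring(10)
  igraph::V(g)$name <- sprintf("r%d", 1:10)
  bins <- assign_degree_bins(g)
  expect_true(all(bins$assignment == 1L))
})

test_that("degree-matched sampling preserves the bin profile", {
  res <- make_annotated_dataset(n_nodes = 300, planted_size = 5, seed = 21)
  net <- res$annotated$network
  bins <- assign_degree_bins(net)
  template <- igraph::V(net)$name[
    !is.na(igraph::V(net)$z)][c(3, 40, 90, 150, 200)]
  for (s in 1:20) {
    draw <- sample_bin_matched_genes(net, bins, template, seed = s)
    expect_length(draw, 5)
    expect_false(anyDuplicated(draw) > 0)
    expect_identical(as.integer(table(bins$assignment[draw])),
                     as.integer(table(bins$assignment[template])))
  }
})

test_that("topology permutation P-value hits the formula floor and is
           reproducible", {
  res <- make_annotated_dataset(n_nodes = 300, planted_size = 6,
                                signal_p_max = 1e-6, seed = 22)
  net <- res$annotated$network
  bins <- assign_degree_bins(net)
  planted <- res$dataset$planted_genes
  p1 <- topo_permutation_pvalue(net, planted, bins, n_perm = 1000,
                                seed = 7)
  expect_equal(p1, 1 / 1001)
  p2 <- topo_permutation_pvalue(net, planted, bins, n_perm = 1000,
                                seed = 7)
  expect_identical(p1, p2)
})

test_that("a module drawn from the degree-matched null is unremarkable", {
  res <- make_annotated_dataset(n_nodes = 300, planted_size = 5,
                                signal_p_max = 1, seed = 23)
  net <- res$annotated$network
  bins <- assign_degree_bins(net)
  template <- igraph::V(net)$name[!is.na(igraph::V(net)$z)][1:6]
  draw <- sample_bin_matched_genes(net, bins, template, seed = 5)
  p <- topo_permutation_pvalue(net, draw, bins, n_perm = 1000, seed = 6)
  expect_gt(p, 0.01); expect_lt(p, 0.99)
})

test_that("a bin smaller than the module demand errors", {
  g <- make_star_graph(z_center = 1, z_good = 1, n_good = 6, n_bad = 0)
  bins <- assign_degree_bins(g)
  # the center is alone in the top bin; demanding two center-bin genes
  # cannot be satisfied
  expect_error(
    topo_permutation_pvalue(g, c("center", "center"), bins,
                            n_perm = 100, seed = 1),
    "fewer weighted genes")
})

test_that("selection requires both stages and merging unions gene sets", {
  ev <- data.frame(
    seed = c("a", "c", "x"), k = c(3, 2, 2),
    score = c(5, 4, 3.5),
    p_norm = c(0.01, 0.02, 0.04),
    p_topo = c(0.001, 0.03, 0.2),
    pass = c(TRUE, TRUE, FALSE),
    genes = c("a,b,c", "c,d", "x,y"), stringsAsFactors = FALSE)
  g <- igraph::graph_from_edgelist(
    matrix(c("a", "b", "b", "c", "c", "d", "x", "y", "m1", "a"),
           ncol = 2, byrow = TRUE), directed = FALSE)
  igraph::V(g)$z <- 1
  merged <- select_and_merge(ev, g, sig_mhc_genes = c("m1", "m2"))
  expect_identical(merged$module_gene_union, c("a", "b", "c", "d"))
  expect_identical(merged$candidate_genes,
                   c("a", "b", "c", "d", "m1")) # m2 not in network
  expect_equal(merged$n_modules, 2)
  # sigMHC gene connected to a module gene keeps its induced edge;
  roles <- igraph::V(merged$extended)$role
  expect_identical(roles[igraph::V(merged$extended)$name == "m1"],
                   "sigMHC_gene")
})

test_that("evaluate_modules runs stage 2 only past stage 1 and flags
           survivors", {
  res <- make_annotated_dataset(n_nodes = 250, planted_size = 6,
                                signal_p_max = 1e-5, seed = 24)
  mods <- search_all(res$annotated$network, search_params())
  ev <- suppressMessages(
    evaluate_modules(mods, res$annotated$network, n_perm = 200, seed = 9))
  expect_equal(nrow(ev), nrow(mods))
  expect_true(all(is.na(ev$p_topo[ev$p_norm >= 0.05])))
  expect_true(all(!is.na(ev$p_topo[ev$p_norm < 0.05])))
  expect_identical(ev$pass,
                   ev$p_norm < 0.05 & !is.na(ev$p_topo) & ev$p_topo < 0.05)
  # deterministic under the same master seed
  ev2 <- suppressMessages(
    evaluate_modules(mods, res$annotated$network, n_perm = 200, seed = 9))
  expect_identical(ev$p_topo, ev2$p_topo)
})
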