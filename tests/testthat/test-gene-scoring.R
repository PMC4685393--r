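make_snp_df <- function(pos, chrom = "1") {
  data.frame(snp_id = sprintf("rs%d", seq_along(pos)), chrom = chrom,
             pos = as.integer(pos),
             p_value = rep(0.5, length(pos)), stringsAsFactors = FALSE)
}

test_that("SNP-to-gene mapping uses closed flanked windows", {
  gene <- data.frame(gene_id = "G1", chrom = "1", start = 100000L,
                     end = 101000L, stringsAsFactors = FALSE)
  hit <- map_snps_to_genes(make_snp_df(80000), gene, flank = 20000)
  expect_named(hit, "G1") # inclusive at start - flank
  miss <- map_snps_to_genes(make_snp_df(79999), gene, flank = 20000)
  expect_length(miss, 0) # one below the boundary
  up <- map_snps_to_genes(make_snp_df(121000), gene, flank = 20000)
  expect_named(up, "G1")
})

test_that("a SNP inside several overlapping windows maps to every gene", {
  genes <- data.frame(gene_id = c("G1", "G2", "G3"), chrom = "1",
                      start = c(90000L, 100000L, 110000L),
                      end = c(95000L, 105000L, 115000L),
                      stringsAsFactors = FALSE)
  snp <- make_snp_df(101000)
  # brute-force interval oracle
  expect_ok <- vapply(seq_len(3), function(i)
    101000 >= genes$start[i] - 20000 && 101000 <= genes$end[i] + 20000,
    logical(1))
  expect_true(all(expect_ok))
  hit <- map_snps_to_genes(snp, genes, flank = 20000)
  expect_setequal(names(hit), c("G1", "G2", "G3"))
})

test_that("duplicate SNP ids are rejected and unknown chromosomes skipped", {
  genes <- data.frame(gene_id = "G1", chrom = "1", start = 1L, end = 10L,
                      stringsAsFactors = FALSE)
  dup <- make_snp_df(c(5, 6))
  dup$snp_id <- c("rs1", "rs1")
  expect_error(map_snps_to_genes(dup, genes), "duplicate")
  odd <- make_snp_df(5)
  odd$chrom <- "Z"
  expect_warning(map_snps_to_genes(odd, genes), "unknown chromosome")
})

test_that("gene statistic is the summed chi-square quantile transform", {
  expect_equal(gene_statistic(0.05), 3.8415, tolerance = 1e-4)
  expect_equal(gene_statistic(1.0), 0.0)
  expect_equal(gene_statistic(c(0.05, 0.05)), 7.6829, tolerance = 1e-4)
  expect_equal(gene_statistic(c(0.2, 0.7)),
               stats::qchisq(0.2, 1, lower.tail = FALSE) +
                 stats::qchisq(0.7, 1, lower.tail = FALSE))
  expect_error(gene_statistic(numeric(0)), "no SNPs")
  expect_error(gene_statistic(c(0.5, 0)), "0, 1")
})

test_that("LD estimation handles degenerate panels", {
  one <- matrix(c(0, 1, 2, 1, 0), nrow = 1,
                dimnames = list("rs1", NULL))
  expect_equal(ld_correlation(one)$matrix, matrix(1, 1, 1,
               dimnames = list("rs1", "rs1")))
  dup <- rbind(rs1 = c(0, 1, 2, 1, 2), rs2 = c(0, 1, 2, 1, 2))
  ld <- ld_correlation(dup)
  expect_equal(ld$matrix[1, 2], 1.0, tolerance = 1e-6)
  expect_gte(min(eigen(ld$matrix, symmetric = TRUE)$values), 0)
  nas <- rbind(rs1 = c(1, 2, 0), rsX = c(NA, NA, NA))
  expect_error(ld_correlation(nas), "rsX")
  mono <- rbind(rs1 = c(0, 1, 2, 1), rs2 = c(1, 1, 1, 1))
  expect_warning(ld2 <- ld_correlation(mono), "monomorphic")
  expect_identical(ld2$snp_ids, "rs1")
})

test_that("LD from an AR(1) panel recovers the lag-1 correlation", {
  blk <- simulate_snp_block(6, rho = 0.8, n_samples = 5000, seed = 31)
  ld <- ld_correlation(blk$genotypes)
  lag1 <- ld$matrix[cbind(1:5, 2:6)]
  expect_lt(mean(abs(lag1 - 0.8)), 0.03)
})

test_that("a single-SNP gene reproduces the SNP P-value within Monte Carlo
           error", {
  p_snp <- 0.01
  stat <- gene_statistic(p_snp)
  res <- gene_pvalue(stat, diag(1), stages = c(1e4, 1e5),
                     escalate_below = 0.2, seed = 42)
  mc_err <- 3 * sqrt(p_snp * (1 - p_snp) / res$n_sims_used)
  expect_lt(abs(res$p_value - p_snp), mc_err)
})

test_that("zero statistic gives P = 1 and the floor is respected", {
  res <- gene_pvalue(0, diag(3), stages = 1e3, escalate_below = numeric(0),
                     seed = 1)
  expect_equal(res$p_value, 1.0)
  big <- gene_pvalue(1e6, diag(2), stages = c(1e3), seed = 1,
                     escalate_below = numeric(0))
  expect_equal(big$p_value, 1 / (1e3 + 1))
})

test_that("larger statistics never get larger P-values under a fixed seed", {
  ld <- diag(4)
  stats_seq <- c(1, 5, 10, 20)
  ps <- vapply(stats_seq, function(s)
    gene_pvalue(s, ld, stages = 1e4, escalate_below = numeric(0),
                seed = 99)$p_value, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("adaptive schedule escalates only for small P-values", {
  weak <- gene_pvalue(gene_statistic(0.5), diag(1),
                      stages = c(1e3, 1e4), escalate_below = 0.1, seed = 3)
  expect_equal(weak$n_sims_used, 1000L)
  strong <- gene_pvalue(gene_statistic(1e-6), diag(1),
                        stages = c(1e3, 1e4), escalate_below = 0.1,
                        seed = 3)
  expect_equal(strong$n_sims_used, 10000L)
})

test_that("score_all_genes omits SNP-less genes and is order-invariant", {
  genes <- data.frame(gene_id = sprintf("G%d", 1:10), chrom = "1",
                      start = seq(1e6, by = 1e6, length.out = 10),
                      end = seq(1e6, by = 1e6, length.out = 10) + 1e4,
                      stringsAsFactors = FALSE)
  # SNPs only in the first 7 gene windows
  snps <- data.frame(snp_id = sprintf("rs%d", 1:7), chrom = "1",
                     pos = as.integer(genes$start[1:7] + 5000),
                     p_value = stats::runif(7), stringsAsFactors = FALSE)
  sc <- score_all_genes(snps, genes, stages = 1e3,
                        escalate_below = numeric(0), seed = 5)
  expect_equal(nrow(sc), 7)
  sc2 <- score_all_genes(snps, genes[rev(seq_len(10)), ], stages = 1e3,
                         escalate_below = numeric(0), seed = 5)
  sc2 <- sc2[match(sc$gene_id, sc2$gene_id), ]
  expect_equal(sc$p_value, sc2$p_value)
})
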