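#' Synthetic-data generator
#'
#' The pipeline was designed around a case/control GWAS and a
#' publication-filtered protein interaction network, neither of which is
#' redistributable. The generator below produces all pipeline inputs with
#' known ground truth: a degree-heterogeneous (scale-free) interactome with
#' per-edge publication counts, a planted connected module of low-P genes, a
#' mock MHC region on chromosome 6, and block-LD SNP data for the gene-level
#' test. Every function is deterministic given its seed.
#'
#' @name synthetic_data
NULL

#' Configuration for the synthetic dataset
#'
#' @param n_nodes number of genes (network nodes).
#' @param attach_edges edges added per node under preferential attachment;
#'   for \code{model = "er"} the expected degree is \code{2 * attach_edges}.
#' @param planted_size size of the planted connected module (>= 2).
#' @param signal_p_max upper bound for planted genes' P-values; planted
#'   P-values are drawn Uniform(0, signal_p_max). \code{1} plants no signal.
#' @param n_mhc number of nodes labeled as lying in the mock MHC region.
#' @param pub_count_range integer pair; per-edge publication counts are drawn
#'   uniformly over this range.
#' @param low_support_frac fraction of edges forced to a single supporting
#'   publication, to exercise edge filtering.
#' @param model "pa" (preferential attachment, default) or "er"
#'   (Erdos-Renyi; the largest connected component is returned) for
#'   degree-homogeneous null calibration.
#' @param seed integer seed; fixed seed implies identical outputs.
#' @return a list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_nodes = 500L, attach_edges = 3L,
                             planted_size = 8L, signal_p_max = 0.001,
                             n_mhc = 0L, pub_count_range = c(1L, 6L),
                             low_support_frac = 0, model = c("pa", "er"),
                             seed = 1L) {
  model <- match.arg(model)
  chk <- function(ok, field, why) {
    if (!ok) stop("invalid synthetic_config: `", field, "` ", why,
                  call. = FALSE)
  }
  chk(is.numeric(n_nodes) && n_nodes >= 2, "n_nodes", "must be >= 2")
  chk(is.numeric(attach_edges) && attach_edges >= 1, "attach_edges",
      "must be >= 1")
  chk(n_nodes >= attach_edges + 1, "n_nodes", "must exceed attach_edges")
  chk(planted_size >= 2 && planted_size <= n_nodes, "planted_size",
      "must be in [2, n_nodes]")
  chk(signal_p_max > 0 && signal_p_max <= 1, "signal_p_max",
      "must be in (0, 1]")
  chk(n_mhc >= 0 && n_mhc <= n_nodes, "n_mhc", "must be in [0, n_nodes]")
  chk(length(pub_count_range) == 2 && pub_count_range[1] >= 1 &&
        pub_count_range[1] <= pub_count_range[2], "pub_count_range",
      "must be an increasing pair of counts >= 1")
  chk(low_support_frac >= 0 && low_support_frac <= 1, "low_support_frac",
      "must be in [0, 1]")
  structure(list(n_nodes = as.integer(n_nodes),
                 attach_edges = as.integer(attach_edges),
                 planted_size = as.integer(planted_size),
                 signal_p_max = signal_p_max, n_mhc = as.integer(n_mhc),
                 pub_count_range = as.integer(pub_count_range),
                 low_support_frac = low_support_frac, model = model,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Simulate an interactome with publication-support edge weights
#'
#' Preferential attachment yields the heavy-tailed degree distribution of
#' real protein interaction networks, which the degree-binned permutation
#' null downstream is designed to correct for. Each edge carries a
#' publication count; a configurable fraction is forced below typical filter
#' thresholds so edge filtering can be exercised.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return an igraph: simple, undirected, connected, with vertex attributes
#'   \code{name} and \code{in_mhc}, and edge attribute \code{n_pubs}.
#' @export
simulate_network <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(derive_seed(config$seed, "network"), {
    g <- if (config$model == "pa") {
      igraph::sample_pa(config$n_nodes, m = config$attach_edges,
                        directed = FALSE)
    } else {
      er <- igraph::sample_gnm(config$n_nodes,
                               config$attach_edges * config$n_nodes)
      comp <- igraph::components(er)
      igraph::induced_subgraph(er, which(comp$membership ==
                                           which.max(comp$csize)))
    }
    g <- igraph::simplify(g)
    n <- igraph::vcount(g)
    igraph::V(g)$name <- sprintf("g%04d", seq_len(n))
    pubs <- sample(seq(config$pub_count_range[1], config$pub_count_range[2]),
                   igraph::ecount(g), replace = TRUE)
    if (config$low_support_frac > 0) {
      k <- floor(config$low_support_frac * igraph::ecount(g))
      if (k > 0) pubs[sample(igraph::ecount(g), k)] <- 1L
    }
    igraph::E(g)$n_pubs <- pubs
    in_mhc <- rep(FALSE, n)
    if (config$n_mhc > 0) in_mhc[sample(n, min(config$n_mhc, n))] <- TRUE
    igraph::V(g)$in_mhc <- in_mhc
    g
  })
}

#' Plant a connected low-P module in a network
#'
#' Grows a connected subgraph of exactly \code{size} nodes by seeded random
#' frontier expansion, assigns its genes P-values Uniform(0, signal_p_max)
#' and all other genes Uniform(0, 1). Frontier candidates are drawn with
#' probability proportional to 1/degree, which counteracts the hub bias of
#' plain snowball growth (in a scale-free graph a hub sits in almost every
#' frontier) and keeps the planted module locally confined — a disease
#' module is a small corner of the interactome, not a neighborhood of its
#' biggest hub. Nodes labeled \code{in_mhc} are avoided so the planted
#' signal is recoverable by the module search (MHC genes are handled by the
#' separate sigMHC rule).
#'
#' @param network an igraph from \code{\link{simulate_network}}.
#' @param size planted module size.
#' @param signal_p_max upper bound of planted P-values; \code{1} means the
#'   planted genes are indistinguishable from background (null datasets).
#' @param seed integer seed.
#' @return a list of class \code{synthetic_dataset} with elements
#'   \code{network}, \code{planted_genes}, \code{gene_pvalues} (named
#'   numeric), \code{truth_labels} (named character, "signal"/"background"),
#'   and \code{seed}.
#' @export
plant_module <- function(network, size, signal_p_max = 0.001, seed = 1L) {
  stopifnot(igraph::is_igraph(network))
  n <- igraph::vcount(network)
  if (size > n) stop("planted module size (", size,
                     ") exceeds network size (", n, ")", call. = FALSE)
  if (size < 1) stop("planted module size must be >= 1", call. = FALSE)
  in_mhc <- if (is.null(igraph::V(network)$in_mhc)) rep(FALSE, n)
            else igraph::V(network)$in_mhc
  with_seed(derive_seed(seed, "plant"), {
    adj <- igraph::adjacent_vertices(network, igraph::V(network))
    adj <- lapply(adj, as.integer)
    eligible <- which(!in_mhc)
    if (length(eligible) < size)
      stop("not enough non-MHC nodes to plant a module of size ", size,
           call. = FALSE)
    # degree-debiased connected growth restricted to non-MHC nodes;
    # restart if stuck
    deg <- igraph::degree(network)
    repeat {
      cur <- eligible[sample.int(length(eligible), 1L,
                                 prob = 1 / deg[eligible])]
      members <- cur
      while (length(members) < size) {
        frontier <- setdiff(unique(unlist(adj[members])), members)
        frontier <- frontier[!in_mhc[frontier]]
        if (length(frontier) == 0L) break
        pick <- if (length(frontier) == 1L) frontier
                else frontier[sample.int(length(frontier), 1L,
                                         prob = 1 / deg[frontier])]
        members <- c(members, pick)
      }
      if (length(members) == size) break
    }
    ids <- igraph::V(network)$name
    planted <- sort(ids[members])
    p <- stats::runif(n)
    names(p) <- ids
    p[planted] <- stats::runif(size, 0, signal_p_max)
    labels <- ifelse(ids %in% planted, "signal", "background")
    names(labels) <- ids
    structure(list(network = network, planted_genes = planted,
                   gene_pvalues = p, truth_labels = labels,
                   seed = as.integer(seed)),
              class = "synthetic_dataset")
  })
}

#' Simulate a block of SNPs in linkage disequilibrium
#'
#' Dosages are continuous (latent Gaussian shifted to mean 1) with AR(1)
#' inter-SNP correlation \code{rho^|i-j|}; discretizing to 0/1/2 would
#' attenuate the Pearson correlations away from the target, and the scoring
#' functions accept fractional dosages. Per-SNP association P-values come
#' from marginal linear regression of a simulated quantitative phenotype on
#' each SNP; \code{effect = 0} gives marginally uniform P-values.
#'
#' @param n_snps number of SNPs in the block.
#' @param rho AR(1) correlation parameter, |rho| < 1.
#' @param n_samples number of samples (columns).
#' @param effect signal strength: the phenotype loads on the block mean with
#'   this coefficient (0 = null).
#' @param seed integer seed.
#' @return list with \code{genotypes} (n_snps x n_samples matrix, rownames
#'   snp ids), \code{p_values} (per SNP), \code{phenotype}.
#' @export
simulate_snp_block <- function(n_snps, rho, n_samples, effect = 0,
                               seed = 1L) {
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  stopifnot(n_snps >= 1, n_samples >= 3)
  if (n_samples <= n_snps)
    warning("n_samples <= n_snps: LD estimates will be rank-deficient")
  with_seed(derive_seed(seed, "snp_block"), {
    z <- matrix(stats::rnorm(n_snps * n_samples), nrow = n_samples)
    if (n_snps > 1 && rho != 0) {
      # AR(1) innovation recursion gives corr(i, j) = rho^|i-j| exactly
      for (j in 2:n_snps)
        z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
    }
    g <- t(z) + 1 # SNPs x samples, mean dosage 1
    rownames(g) <- sprintf("rs%05d", seq_len(n_snps))
    y <- effect * rowMeans(scale(t(g))) + stats::rnorm(n_samples)
    pv <- vapply(seq_len(n_snps), function(i) {
      x <- g[i, ]
      if (stats::sd(x) == 0) return(1)
      r <- stats::cor(x, y)
      tt <- r * sqrt((n_samples - 2) / (1 - r^2))
      2 * stats::pt(abs(tt), df = n_samples - 2, lower.tail = FALSE)
    }, numeric(1))
    names(pv) <- rownames(g)
    list(genotypes = g, p_values = pv, phenotype = y)
  })
}

#' Write a synthetic dataset as pipeline input files
#'
#' Emits, in `directory`: \code{association.tsv} (SNP CHR POS P; one tag SNP
#' per gene carrying the gene's P-value), \code{genes.tsv} (GENE CHR START
#' END, 1-based closed), \code{interactions.tsv} (A B PUBS with
#' pipe-separated synthetic publication ids), and \code{truth.tsv}
#' (gene_id TAB label). MHC-labeled genes are laid out inside the default
#' MHC region on chromosome 6 so the sigMHC rule fires on read-back.
#'
#' @param dataset a \code{synthetic_dataset}.
#' @param directory output directory (created if missing).
#' @return invisibly, the named character vector of file paths.
#' @export
write_fixture <- function(dataset, directory) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  g <- dataset$network
  ids <- igraph::V(g)$name
  in_mhc <- if (is.null(igraph::V(g)$in_mhc)) rep(FALSE, length(ids))
            else igraph::V(g)$in_mhc
  mhc <- mhc_region_default()
  genes <- data.frame(GENE = ids, CHR = "1",
                      START = 0L, END = 0L, stringsAsFactors = FALSE)
  # non-MHC genes tile chromosomes 1-22 (MHC chromosome excluded), spaced
  # far beyond the 20 kb flank so tag SNPs map uniquely
  non <- which(!in_mhc)
  chr_pool <- setdiff(as.character(1:22), mhc$chrom)
  genes$CHR[non] <- chr_pool[(seq_along(non) - 1L) %% length(chr_pool) + 1L]
  slot <- (seq_along(non) - 1L) %/% length(chr_pool)
  genes$START[non] <- 1000000L + slot * 1000000L
  genes$END[non] <- genes$START[non] + 10000L
  if (any(in_mhc)) {
    m <- which(in_mhc)
    genes$CHR[m] <- mhc$chrom
    genes$START[m] <- as.integer(mhc$start + 10000 +
                                   (seq_along(m) - 1L) * 100000L)
    genes$END[m] <- genes$START[m] + 10000L
    if (any(genes$END[m] > mhc$end))
      stop("too many MHC genes to place inside the mock MHC region",
           call. = FALSE)
  }
  assoc <- data.frame(SNP = paste0("tag_", ids), CHR = genes$CHR,
                      POS = genes$START + 5000L,
                      P = unname(dataset$gene_pvalues[ids]),
                      stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g)
  pubs <- vapply(igraph::E(g)$n_pubs, function(k)
    paste(paste0("pmid:", seq_len(k)), collapse = "|"), character(1))
  inter <- data.frame(A = el[, 1], B = el[, 2], PUBS = pubs,
                      stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = ids,
                      label = unname(dataset$truth_labels[ids]),
                      stringsAsFactors = FALSE)
  paths <- c(association = file.path(directory, "association.tsv"),
             genes = file.path(directory, "genes.tsv"),
             interactions = file.path(directory, "interactions.tsv"),
             truth = file.path(directory, "truth.tsv"))
  wr <- function(df, path) utils::write.table(
    df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  wr(assoc, paths["association"]); wr(genes, paths["genes"])
  wr(inter, paths["interactions"]); wr(truth, paths["truth"])
  invisible(paths)
}
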