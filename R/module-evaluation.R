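#' Two-stage module significance evaluation
#'
#' Stage 1 assigns each module an upper-tail P-value against an empirical
#' null: the full set of module scores is median-centered and a normal is
#' fitted to its central bulk (central matching), so the bulk of ordinary
#' modules defines "chance" and only the right tail stands out. Stage 2
#' controls topology bias: high-degree hubs are absorbed by the greedy
#' search more easily regardless of signal, so each surviving module is
#' compared against random gene sets matching its size and degree-bin
#' profile. Modules passing both tests (p < 0.05 each) form the final set;
#' their union plus the sigMHC-genes gives the candidate-gene subnetwork.
#'
#' @name module_evaluation
NULL

#' Fit an empirical null to module scores by central matching
#'
#' Scores are median-centered; empirical quantiles of the central band
#' (default the 25th-75th percentiles) are regressed on standard normal
#' quantiles, giving a location (mu, intercept) and scale (sigma, slope)
#' that are insensitive to a signal-bearing right tail.
#'
#' @param scores numeric module scores (>= 50 recommended; fewer warns).
#' @param band central quantile band used for the fit.
#' @return list of class \code{null_distribution}: mu, sigma, method,
#'   n_scores, center (the subtracted median).
#' @export
fit_empirical_null <- function(scores, band = c(0.25, 0.75)) {
  stopifnot(is.numeric(scores), length(band) == 2, band[1] < band[2])
  n <- length(scores)
  if (n < 50) warning("empirical null fitted to only ", n, " scores")
  med <- stats::median(scores)
  centered <- scores - med
  if (stats::sd(centered) == 0)
    stop("degenerate (constant) module scores: cannot fit an empirical null",
         call. = FALSE)
  probs <- seq(band[1], band[2], length.out = 11)
  qe <- unname(stats::quantile(centered, probs, type = 7))
  qt <- stats::qnorm(probs)
  fit <- stats::lm.fit(cbind(1, qt), qe)
  mu <- fit$coefficients[1]
  sigma <- fit$coefficients[2]
  if (!is.finite(sigma) || sigma <= 0)
    stop("empirical null fit failed: non-positive scale", call. = FALSE)
  structure(list(mu = unname(mu), sigma = unname(sigma),
                 method = "central_matching", n_scores = n, center = med),
            class = "null_distribution")
}

#' Stage-1 P-values from the empirical null
#'
#' p = 1 - Phi((score - center - mu) / sigma), upper tail.
#'
#' @param scores module scores (raw, uncentered).
#' @param null a \code{\link{fit_empirical_null}} result.
#' @return numeric P-values.
#' @export
normal_stage_pvalues <- function(scores, null) {
  stopifnot(inherits(null, "null_distribution"), null$sigma > 0)
  stats::pnorm((scores - null$center - null$mu) / null$sigma,
               lower.tail = FALSE)
}

#' Assign network nodes to degree quartile bins
#'
#' All nodes are split into four groups at the quartiles of the degree
#' distribution; ties go to the lower bin. Degenerate distributions
#' (coincident quartiles) leave upper bins empty and every node in the
#' lowest applicable bin.
#'
#' @param network igraph.
#' @return list of class \code{degree_bins}: boundaries (3 cut points),
#'   assignment (named integer vector, bins 1-4).
#' @export
assign_degree_bins <- function(network) {
  stopifnot(igraph::vcount(network) > 0)
  deg <- igraph::degree(network)
  cuts <- unname(stats::quantile(deg, c(0.25, 0.5, 0.75), type = 7))
  bin <- 1L + (deg > cuts[1]) + (deg > cuts[2]) + (deg > cuts[3])
  names(bin) <- igraph::V(network)$name
  structure(list(boundaries = cuts, assignment = bin),
            class = "degree_bins")
}

#' Degree-matched random gene set
#'
#' Draws, for each gene of a template set, a random distinct weighted gene
#' from the same degree bin (without replacement within the draw). This is
#' the stage-2 null generator, exposed for calibration.
#'
#' @param network annotated igraph.
#' @param bins a \code{\link{assign_degree_bins}} result.
#' @param template_genes gene ids whose bin profile is matched.
#' @param seed integer seed.
#' @return character vector of gene ids (same length as the template).
#' @export
sample_bin_matched_genes <- function(network, bins, template_genes,
                                     seed = 1L) {
  pools <- stage2_pools(network, bins)
  with_seed(seed, draw_matched(pools, bin_profile(bins, template_genes)))
}

# Weighted genes per bin (unweighted sigMHC genes carry no z and cannot be
# scored, so they are not sampled).
stage2_pools <- function(network, bins) {
  ids <- igraph::V(network)$name
  z <- igraph::V(network)$z
  weighted <- !is.na(z)
  names(z) <- ids
  pool_ids <- split(ids[weighted], bins$assignment[ids[weighted]])
  list(pool_ids = pool_ids, z = z)
}

bin_profile <- function(bins, genes) {
  b <- bins$assignment[genes]
  if (anyNA(b)) stop("module gene(s) not in the degree-bin assignment: ",
                     paste(genes[is.na(b)], collapse = ", "), call. = FALSE)
  table(b)
}

draw_matched <- function(pools, profile) {
  unlist(lapply(names(profile), function(b) {
    pool <- pools$pool_ids[[b]]
    m <- profile[[b]]
    if (is.null(pool) || length(pool) < m)
      stop("degree bin ", b, " holds fewer weighted genes (",
           length(pool), ") than the module needs (", m, ")",
           call. = FALSE)
    pool[sample.int(length(pool), m)]
  }), use.names = FALSE)
}

#' Stage-2 topology permutation P-value
#'
#' Scores \code{n_perm} random degree-matched gene sets and returns
#' p = (#\{random score >= observed\} + 1) / (n_perm + 1).
#'
#' @param network annotated igraph.
#' @param module_genes member gene ids of the observed module.
#' @param bins degree bins over the network.
#' @param n_perm number of resamples (>= 100; default 10,000).
#' @param seed integer seed.
#' @return P-value (floor 1/(n_perm + 1)).
#' @export
topo_permutation_pvalue <- function(network, module_genes, bins,
                                    n_perm = 10000L, seed = 1L) {
  stopifnot(n_perm >= 100)
  pools <- stage2_pools(network, bins)
  z <- pools$z[module_genes]
  if (anyNA(z)) stop("module contains genes without z scores",
                     call. = FALSE)
  observed <- module_score(z)
  profile <- bin_profile(bins, module_genes)
  k <- length(module_genes)
  pool_z <- lapply(names(profile), function(b)
    unname(pools$z[pools$pool_ids[[b]]]))
  m_b <- as.integer(profile)
  for (j in seq_along(pool_z))
    if (length(pool_z[[j]]) < m_b[j])
      stop("degree bin ", names(profile)[j],
           " holds fewer weighted genes (", length(pool_z[[j]]),
           ") than the module needs (", m_b[j], ")", call. = FALSE)
  with_seed(seed, {
    null_scores <- vapply(seq_len(n_perm), function(i) {
      s <- 0
      for (j in seq_along(pool_z)) {
        pz <- pool_z[[j]]
        s <- s + sum(pz[sample.int(length(pz), m_b[j])])
      }
      s / sqrt(k)
    }, numeric(1))
    empirical_pvalue(sum(null_scores >= observed), n_perm)
  })
}

#' Evaluate all modules (both stages)
#'
#' Stage 1 fits the empirical null to all module scores and keeps modules
#' with p_norm < alpha; stage 2 runs the degree-matched permutation on the
#' survivors only. Per-module permutation seeds are derived from the master
#' seed and the module's gene-set key.
#'
#' @param modules data.frame from \code{\link{search_all}}.
#' @param network annotated igraph.
#' @param bins optional precomputed degree bins (default: computed here).
#' @param n_perm stage-2 resamples (default 10,000).
#' @param alpha per-stage significance threshold (default 0.05).
#' @param seed master integer seed.
#' @return data.frame: seed, k, score, p_norm, p_topo (NA where stage 2 was
#'   not reached), pass, genes. Attribute \code{null} holds the fitted
#'   null distribution.
#' @export
evaluate_modules <- function(modules, network, bins = NULL,
                             n_perm = 10000L, alpha = 0.05, seed = 1L) {
  if (nrow(modules) == 0) {
    out <- cbind(modules[, c("seed", "k", "score")],
                 p_norm = numeric(0), p_topo = numeric(0),
                 pass = logical(0), genes = character(0))
    return(out)
  }
  if (is.null(bins)) bins <- assign_degree_bins(network)
  null <- fit_empirical_null(modules$score)
  p_norm <- normal_stage_pvalues(modules$score, null)
  p_topo <- rep(NA_real_, nrow(modules))
  stage2 <- which(p_norm < alpha)
  for (i in stage2) {
    genes <- module_genes(modules$genes[i])[[1]]
    p_topo[i] <- topo_permutation_pvalue(
      network, genes, bins, n_perm = n_perm,
      seed = derive_seed(seed, modules$genes[i]))
  }
  out <- data.frame(seed = modules$seed, k = modules$k,
                    score = modules$score, p_norm = p_norm,
                    p_topo = p_topo,
                    pass = p_norm < alpha & !is.na(p_topo) & p_topo < alpha,
                    genes = modules$genes, stringsAsFactors = FALSE)
  attr(out, "null") <- null
  out
}

#' Merge surviving modules and sigMHC-genes into the candidate subnetwork
#'
#' @param evaluated data.frame from \code{\link{evaluate_modules}}.
#' @param network annotated igraph.
#' @param sig_mhc_genes character vector of sigMHC gene ids.
#' @return list: \code{module_gene_union} (sorted ids of surviving
#'   modules), \code{candidate_genes} (union plus sigMHC),
#'   \code{subnetwork} (induced igraph on the module union),
#'   \code{extended} (induced igraph on the candidates, vertex attribute
#'   \code{role} in \{module_gene, sigMHC_gene\}), \code{n_modules}.
#' @export
select_and_merge <- function(evaluated, network,
                             sig_mhc_genes = character()) {
  surv <- evaluated[evaluated$pass, , drop = FALSE]
  union_genes <- sort(unique(unlist(module_genes(surv$genes))))
  if (length(union_genes) == 0)
    message("no module passed both evaluation stages")
  ids <- igraph::V(network)$name
  sub <- igraph::induced_subgraph(network, which(ids %in% union_genes))
  cand <- sort(unique(c(union_genes, intersect(sig_mhc_genes, ids))))
  ext <- igraph::induced_subgraph(network, which(ids %in% cand))
  role <- ifelse(igraph::V(ext)$name %in% union_genes, "module_gene",
                 "sigMHC_gene")
  igraph::V(ext)$role <- role
  list(module_gene_union = union_genes, candidate_genes = cand,
       subnetwork = sub, extended = ext, n_modules = nrow(surv))
}
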