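#' Dense module search
#'
#' Greedy seed-and-grow maximization of the node-weighted module score. Each
#' gene's P-value becomes a z-score via the inverse normal CDF; a module of
#' k genes scores Zm = sum(z) / sqrt(k). From every eligible seed the module
#' repeatedly absorbs the neighboring weighted node yielding the maximum new
#' score, accepting a step only when the score grows by more than a factor
#' (1 + r); growth then stops. This is the dense-module-search procedure of
#' dmGWAS with its default admission rule.
#'
#' @name module_search
NULL

#' Inverse-normal transform of a gene P-value
#'
#' z = qnorm(1 - p), computed on the upper tail for numerical precision.
#' The transform is clamped symmetrically to |z| <= qnorm(1e-16, lower.tail
#' = FALSE): P-values below 1e-16 are floored, and an empirical P of
#' exactly 1 (every Monte Carlo draw at least as large as the statistic)
#' maps to the lower clamp instead of -Inf, keeping module scores finite.
#'
#' @param p P-value(s) in (0, 1].
#' @return z score(s); non-increasing in p.
#' @export
z_transform <- function(p) {
  if (any(p <= 0 | p > 1)) stop("P-values must lie in (0, 1]",
                                call. = FALSE)
  z <- stats::qnorm(pmax(p, 1e-16), lower.tail = FALSE)
  zmax <- stats::qnorm(1e-16, lower.tail = FALSE)
  pmin(pmax(z, -zmax), zmax)
}

#' Module score Zm
#'
#' @param z_values member z-scores (non-empty, no NA).
#' @return sum(z) / sqrt(k).
#' @export
module_score <- function(z_values) {
  if (length(z_values) == 0) stop("empty module", call. = FALSE)
  if (anyNA(z_values)) stop("module contains unweighted genes",
                            call. = FALSE)
  sum(z_values) / sqrt(length(z_values))
}

#' Search parameters
#'
#' @param r increment rate: a growth step is accepted only if the new score
#'   exceeds the old score times (1 + r). Default 0.1 (dmGWAS default).
#' @param d candidate neighborhood distance from the current module, 1
#'   (immediate neighbors, default) or 2. A distance-2 candidate is admitted
#'   together with its best connecting intermediate, so modules always
#'   induce a connected subgraph.
#' @param exclude_seeds gene ids never used as seeds (typically the
#'   sigMHC-genes).
#' @return list of class \code{search_params}.
#' @export
search_params <- function(r = 0.1, d = 1L, exclude_seeds = character()) {
  stopifnot(r >= 0, d %in% c(1L, 2L))
  structure(list(r = r, d = as.integer(d),
                 exclude_seeds = as.character(exclude_seeds)),
            class = "search_params")
}

# Internal search context: integer adjacency over weighted nodes only.
# Unweighted (sigMHC) nodes carry no z, so the score is undefined for them;
# they are excluded from growth and rejoin at the merge step.
search_context <- function(network) {
  ids <- igraph::V(network)$name
  z <- igraph::V(network)$z
  if (is.null(z)) stop("network is not annotated with z scores",
                       call. = FALSE)
  adj <- lapply(igraph::adjacent_vertices(network, igraph::V(network)),
                as.integer)
  weighted <- !is.na(z)
  # drop unweighted nodes from every neighbor list
  adj <- lapply(adj, function(v) v[weighted[v]])
  list(ids = ids, z = z, adj = adj, weighted = weighted)
}

grow_module_ctx <- function(ctx, seed_idx, params) {
  members <- seed_idx
  zsum <- ctx$z[seed_idx]
  score <- zsum
  in_mod <- rep(FALSE, length(ctx$ids))
  in_mod[seed_idx] <- TRUE
  repeat {
    near <- unique(unlist(ctx$adj[members]))
    near <- near[!in_mod[near]]
    if (length(near) == 0L) break
    k1 <- length(members) + 1L
    new_scores <- (zsum + ctx$z[near]) / sqrt(k1)
    picks <- as.list(near)
    if (params$d == 2L) {
      # distance-2 candidates enter together with their best connecting
      # intermediate so the module stays an induced connected subgraph
      far <- setdiff(unique(unlist(ctx$adj[near])), c(near, members))
      far <- far[!in_mod[far]]
      if (length(far) > 0L) {
        k2 <- length(members) + 2L
        for (f in far) {
          mids <- intersect(ctx$adj[[f]], near)
          zmid <- max(ctx$z[mids])
          mid <- mids[ctx$z[mids] == zmid][1L]
          new_scores <- c(new_scores, (zsum + ctx$z[f] + zmid) / sqrt(k2))
          picks <- c(picks, list(c(mid, f)))
        }
      }
    }
    best <- max(new_scores)
    if (!(best > score * (1 + params$r))) break
    at_best <- which(new_scores == best)
    if (length(at_best) > 1L) {
      keys <- vapply(picks[at_best], function(v)
        paste(sort(ctx$ids[v]), collapse = ","), character(1))
      at_best <- at_best[order(keys)][1L]
    }
    add <- picks[[at_best]]
    members <- c(members, add)
    in_mod[add] <- TRUE
    zsum <- zsum + sum(ctx$z[add])
    score <- best
  }
  list(members = members, score = score)
}

#' Grow one module from a seed
#'
#' @param network annotated igraph (vertex attributes name, z).
#' @param seed seed gene id; must be a weighted node.
#' @param params a \code{\link{search_params}}.
#' @return list of class \code{module}: seed, genes (sorted ids), k, score.
#' @export
grow_module <- function(network, seed, params = search_params()) {
  ctx <- search_context(network)
  i <- match(seed, ctx$ids)
  if (is.na(i)) stop("seed gene not in network: ", seed, call. = FALSE)
  if (!ctx$weighted[i]) stop("seed gene is unweighted: ", seed,
                             call. = FALSE)
  res <- grow_module_ctx(ctx, i, params)
  structure(list(seed = seed, genes = sort(ctx$ids[res$members]),
                 k = length(res$members), score = res$score),
            class = "module")
}

#' Search modules from every eligible seed
#'
#' Every weighted node except those in \code{params$exclude_seeds} seeds one
#' growth. Modules with identical gene sets are collapsed, keeping the first
#' seed in sorted order; the result is ordered by descending score, ties
#' broken by seed id.
#'
#' @param network annotated igraph.
#' @param params a \code{\link{search_params}}.
#' @return data.frame: seed, k, score, genes (comma-joined sorted ids).
#' @export
search_all <- function(network, params = search_params()) {
  ctx <- search_context(network)
  seeds <- which(ctx$weighted & !(ctx$ids %in% params$exclude_seeds))
  seeds <- seeds[order(ctx$ids[seeds])]
  seen <- new.env(hash = TRUE, parent = emptyenv())
  rows <- vector("list", length(seeds))
  n_out <- 0L
  for (i in seeds) {
    res <- grow_module_ctx(ctx, i, params)
    genes <- sort(ctx$ids[res$members])
    key <- paste(genes, collapse = ",")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    n_out <- n_out + 1L
    rows[[n_out]] <- data.frame(seed = ctx$ids[i],
                                k = length(res$members),
                                score = res$score, genes = key,
                                stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[seq_len(n_out)])
  if (is.null(out))
    return(data.frame(seed = character(), k = integer(), score = numeric(),
                      genes = character(), stringsAsFactors = FALSE))
  out <- out[order(-out$score, out$seed), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split a comma-joined gene field back into ids
#'
#' @param genes character vector of comma-joined gene lists.
#' @return list of character vectors.
#' @export
module_genes <- function(genes) strsplit(genes, ",", fixed = TRUE)
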