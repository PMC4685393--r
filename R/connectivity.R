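#' Direct-interconnectivity permutation test
#'
#' Tests whether a gene set is more densely directly connected in the
#' interactome than expected from its members' degrees alone. The null
#' keeps the network topology fixed and permutes node labels only among
#' nodes of equal degree, so every null network has exactly the original
#' structure and per-protein binding degree; the null connectivity is then
#' entirely a function of degree, as in the DAPPLE approach.
#'
#' @name connectivity_test
NULL

#' Count direct edges within a gene set
#'
#' @param network igraph.
#' @param genes gene ids; ids absent from the network are dropped with a
#'   message.
#' @return number of edges with both endpoints in \code{genes}.
#' @export
direct_edge_count <- function(network, genes) {
  ids <- igraph::V(network)$name
  missing <- setdiff(genes, ids)
  if (length(missing) > 0)
    message(length(missing), " gene(s) not in network dropped: ",
            paste(utils::head(missing, 5), collapse = ", "))
  inset <- ids %in% genes
  el <- igraph::as_edgelist(network, names = FALSE)
  sum(inset[el[, 1]] & inset[el[, 2]])
}

#' Permute node labels within exact-degree classes
#'
#' Returns a network with identical topology whose vertex names are
#' permuted uniformly at random among nodes of equal degree; a node with a
#' unique degree keeps its label, and every label's degree is unchanged.
#'
#' @param network igraph.
#' @param seed integer seed.
#' @return relabeled igraph.
#' @export
permute_labels_within_degree <- function(network, seed = 1L) {
  deg <- igraph::degree(network)
  nm <- igraph::V(network)$name
  with_seed(seed, {
    new_nm <- nm
    for (cls in split(seq_along(deg), deg)) {
      if (length(cls) > 1)
        new_nm[cls] <- nm[cls[sample.int(length(cls))]]
    }
    igraph::set_vertex_attr(network, "name", value = new_nm)
  })
}

#' Connectivity P-value by degree-preserving label permutation
#'
#' p = (#\{null edge count >= observed\} + 1) / (n_perm + 1) over n_perm
#' label permutations.
#'
#' @param network igraph.
#' @param genes gene ids (>= 2 after dropping ids absent from the network).
#' @param n_perm number of permuted networks (>= 100; default 10,000).
#' @param seed integer seed.
#' @return list of class \code{connectivity_result}: observed_edges,
#'   null_edge_counts, p_value, n_perm, n_genes_used.
#' @export
connectivity_pvalue <- function(network, genes, n_perm = 10000L,
                                seed = 1L) {
  stopifnot(n_perm >= 100)
  ids <- igraph::V(network)$name
  genes <- intersect(genes, ids)
  if (length(genes) < 2)
    stop("fewer than 2 query genes mapped to the network", call. = FALSE)
  inset <- ids %in% genes
  el <- igraph::as_edgelist(network, names = FALSE)
  observed <- sum(inset[el[, 1]] & inset[el[, 2]])
  classes <- split(seq_along(ids), igraph::degree(network))
  classes <- classes[vapply(classes, length, integer(1)) > 1]
  nulls <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      ind <- inset
      for (cls in classes) ind[cls] <- inset[cls[sample.int(length(cls))]]
      sum(ind[el[, 1]] & ind[el[, 2]])
    }, numeric(1))
  })
  structure(list(observed_edges = observed, null_edge_counts = nulls,
                 p_value = empirical_pvalue(sum(nulls >= observed), n_perm),
                 n_perm = as.integer(n_perm),
                 n_genes_used = length(genes)),
            class = "connectivity_result")
}
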