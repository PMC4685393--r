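#' Node-weighted interactome construction
#'
#' Parses protein-protein interactions with their supporting publications,
#' filters to well-supported edges, attaches gene-level association evidence
#' as node weights (z = inverse-normal of 1 - p), and flags significant MHC
#' genes (sigMHC-genes): genes inside the MHC region with gene P < alpha are
#' kept in the network for integrity but left unweighted and are never used
#' as search seeds, because the MHC's extreme LD and gene density would
#' otherwise dominate the module search.
#'
#' @name network_builder
NULL

#' Default MHC region (classical MHC, GRCh37)
#'
#' Chromosome 6:28,477,797-33,448,354. Configurable wherever it is consumed;
#' gene coordinates are assumed to be on the same assembly.
#'
#' @return list with chrom, start, end.
#' @export
mhc_region_default <- function() {
  list(chrom = "6", start = 28477797, end = 33448354)
}

#' Parse an interaction file
#'
#' Accepts a TSV with header \code{A B PUBS} (PUBS pipe-separated
#' publication ids) or a MITAB 2.5/2.6 file (first line starting with "#";
#' interactor ids from columns 1-2 with their database prefix stripped,
#' publications from column 9). Pairs are canonicalized as unordered:
#' duplicate pairs are merged by publication-set union; self-loops are
#' dropped with a reported count.
#'
#' @param path file path.
#' @return data.frame with columns protein_a, protein_b (protein_a <
#'   protein_b), publications (pipe-joined unique ids), n_pubs. Attribute
#'   \code{n_self_loops} records dropped self-interactions.
#' @export
parse_interactions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  mitab <- startsWith(first, "#ID") || startsWith(first, "#id") ||
    length(strsplit(first, "\t", fixed = TRUE)[[1]]) >= 15
  if (mitab) {
    df <- utils::read.delim(path, header = FALSE, comment.char = "",
                            stringsAsFactors = FALSE, quote = "")
    if (startsWith(as.character(df[1, 1]), "#")) df <- df[-1, , drop = FALSE]
    if (ncol(df) < 9) stop("MITAB file has fewer than 9 columns: ", path,
                           call. = FALSE)
    strip <- function(x) sub("^[^:]+:", "", x)
    a <- strip(as.character(df[[1]]))
    b <- strip(as.character(df[[2]]))
    pubs <- as.character(df[[9]])
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("A", "B", "PUBS")
    if (!all(need %in% names(df)))
      stop("interaction table must have header A B PUBS: ", path,
           call. = FALSE)
    bad <- which(is.na(df$A) | is.na(df$B) | df$A == "" | df$B == "")
    if (length(bad))
      stop("malformed interaction line ", bad[1] + 1L, " in ", path,
           call. = FALSE)
    a <- as.character(df$A); b <- as.character(df$B)
    pubs <- as.character(df$PUBS)
  }
  loops <- a == b
  n_loops <- sum(loops)
  if (n_loops > 0) message(n_loops, " self-loop(s) dropped")
  a <- a[!loops]; b <- b[!loops]; pubs <- pubs[!loops]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  pub_sets <- tapply(pubs, key, function(x)
    sort(unique(unlist(strsplit(x, "|", fixed = TRUE)))), simplify = FALSE)
  keys <- names(pub_sets)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    protein_a = vapply(parts, `[`, character(1), 1L),
    protein_b = vapply(parts, `[`, character(1), 2L),
    publications = vapply(pub_sets, paste, character(1), collapse = "|"),
    n_pubs = vapply(pub_sets, length, integer(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_self_loops") <- n_loops
  out
}

#' Filter interactions by publication support and build the graph
#'
#' Keeps edges supported by at least \code{min_pubs} unique publications —
#' the standard guard against interactions seen in a single experiment —
#' and drops nodes left without any edge.
#'
#' @param records data.frame from \code{\link{parse_interactions}}.
#' @param min_pubs minimum publication count (default 2).
#' @return simple undirected igraph with edge attribute \code{n_pubs}.
#' @export
filter_edges <- function(records, min_pubs = 2L) {
  stopifnot(min_pubs >= 1)
  keep <- records$n_pubs >= min_pubs
  if (!any(keep))
    stop("publication filter at min_pubs = ", min_pubs,
         " leaves an empty network", call. = FALSE)
  kept <- records[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = kept$protein_a, to = kept$protein_b,
               n_pubs = kept$n_pubs, stringsAsFactors = FALSE),
    directed = FALSE)
  message("publication filter (>= ", min_pubs, "): ", igraph::vcount(g),
          " nodes, ", igraph::ecount(g), " edges")
  g
}

# Does gene i's unextended [start, end] overlap the MHC region? Region
# membership is a property of the gene body, not of its SNP-capture window.
gene_in_mhc <- function(genes, mhc) {
  genes$chrom == mhc$chrom & genes$start <= mhc$end & genes$end >= mhc$start
}

#' Attach gene-level evidence to the network
#'
#' Nodes with a gene P-value get z = qnorm(1 - p) and \code{weighted =
#' TRUE}, except genes lying in the MHC region with p < alpha_mhc: these
#' become sigMHC-genes (kept, unweighted, no z, never a seed). Nodes with no
#' gene P-value at all are removed.
#'
#' @param network igraph from \code{\link{filter_edges}}.
#' @param gene_scores data.frame with gene_id and p_value (e.g. from
#'   \code{\link{score_all_genes}}).
#' @param gene_models optional gene model data.frame used to decide MHC
#'   membership; nodes absent from it are treated as non-MHC.
#' @param mhc MHC region (list chrom/start/end); default GRCh37 classical
#'   MHC.
#' @param alpha_mhc sigMHC significance threshold (default 0.05).
#' @return list with \code{network} (igraph with vertex attributes p_value,
#'   z, in_mhc, sig_mhc, weighted) and \code{sig_mhc_genes} (character).
#' @export
annotate_weights <- function(network, gene_scores, gene_models = NULL,
                             mhc = mhc_region_default(), alpha_mhc = 0.05) {
  ids <- igraph::V(network)$name
  idx <- match(ids, gene_scores$gene_id)
  unmatched <- sum(is.na(idx))
  if (unmatched > 0)
    message(unmatched, " network node(s) without a gene P-value removed")
  p <- gene_scores$p_value[idx]
  in_mhc <- rep(FALSE, length(ids))
  if (!is.null(gene_models)) {
    gm_idx <- match(ids, gene_models$gene_id)
    hit <- !is.na(gm_idx)
    in_mhc[hit] <- gene_in_mhc(gene_models[gm_idx[hit], , drop = FALSE], mhc)
  }
  sig_mhc <- !is.na(p) & in_mhc & p < alpha_mhc
  weighted <- !is.na(p) & !sig_mhc
  keep <- weighted | sig_mhc
  g <- igraph::induced_subgraph(network, which(keep))
  kids <- igraph::V(g)$name
  kidx <- match(kids, ids)
  igraph::V(g)$p_value <- p[kidx]
  igraph::V(g)$in_mhc <- in_mhc[kidx]
  igraph::V(g)$sig_mhc <- sig_mhc[kidx]
  igraph::V(g)$weighted <- weighted[kidx]
  z <- rep(NA_real_, length(kids))
  z[weighted[kidx]] <- z_transform(p[kidx][weighted[kidx]])
  igraph::V(g)$z <- z
  list(network = g, sig_mhc_genes = sort(kids[sig_mhc[kidx]]))
}

#' Write a network as an edge-list TSV
#'
#' @param network igraph.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_edge_list <- function(network, path) {
  el <- igraph::as_edgelist(network)
  df <- data.frame(A = el[, 1], B = el[, 2], stringsAsFactors = FALSE)
  if (!is.null(igraph::E(network)$n_pubs))
    df$N_PUBS <- igraph::E(network)$n_pubs
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network as GraphML with node attributes
#'
#' @param network igraph.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}
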