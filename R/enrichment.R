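#' Gene-set over-representation analysis
#'
#' One-sided Fisher exact tests of a query gene list against a gene-set
#' collection (GMT) over an explicit background universe, with
#' Benjamini-Hochberg adjustment. The background defaults, at the pipeline
#' level, to all weighted genes of the node-weighted network — the universe
#' the modules were searched in.
#'
#' @name enrichment
NULL

#' Read a GMT gene-set file
#'
#' Standard format: term id, description, then tab-separated member genes.
#'
#' @param path file path.
#' @return named list of class \code{gene_set_collection}; each element has
#'   \code{name} (description) and \code{genes}.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("GMT line with fewer than 3 fields",
                            call. = FALSE)
    list(name = f[2], genes = unique(f[-(1:2)]))
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  if (any(vapply(sets, function(s) length(s$genes) == 0, logical(1))))
    stop("empty gene set in GMT", call. = FALSE)
  structure(sets, class = "gene_set_collection")
}

# Upper-tail hypergeometric probability P(X >= overlap); identical to the
# one-sided Fisher exact P for the 2x2 over-representation table. With
# ease = TRUE the DAVID-style EASE variant scores overlap - 1.
hyper_tail_p <- function(overlap, query_size, set_size, background_size,
                         ease = FALSE) {
  x <- if (ease) pmax(overlap - 1, 0) else overlap
  stats::phyper(x - 1, set_size, background_size - set_size, query_size,
                lower.tail = FALSE)
}

#' Fisher-exact over-representation test per gene set
#'
#' @param query character vector of query genes; genes outside the
#'   background are dropped with a warning.
#' @param collection a \code{\link{read_gmt}} result (or a named list of
#'   \code{list(name, genes)}).
#' @param background character vector: the gene universe. Gene-set members
#'   outside the background are ignored.
#' @param ease use the conservative EASE-modified score (overlap - 1);
#'   default plain Fisher.
#' @return data.frame sorted by p_adj then p: term, name, overlap,
#'   query_size, set_size, background_size, p, p_adj, overlap_genes.
#' @export
fisher_enrichment <- function(query, collection, background,
                              ease = FALSE) {
  background <- unique(background)
  query <- unique(query)
  outside <- setdiff(query, background)
  if (length(outside) > 0)
    warning(length(outside), " query gene(s) outside the background ",
            "dropped")
  query <- intersect(query, background)
  if (length(query) == 0)
    stop("empty query after background intersection", call. = FALSE)
  rows <- lapply(names(collection), function(term) {
    set <- intersect(collection[[term]]$genes, background)
    ov <- intersect(query, set)
    data.frame(term = term, name = collection[[term]]$name,
               overlap = length(ov), query_size = length(query),
               set_size = length(set),
               background_size = length(background),
               p = hyper_tail_p(length(ov), length(query), length(set),
                                length(background), ease = ease),
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out <- out[order(out$p_adj, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("term", "name", "overlap", "query_size", "set_size",
          "background_size", "p", "p_adj", "overlap_genes")]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a thin wrapper over
#' \code{stats::p.adjust(method = "BH")} kept as a named step of the
#' pipeline.
#'
#' @param pvalues numeric vector in [0, 1].
#' @return adjusted P-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH")
}

#' Select enriched terms
#'
#' @param results data.frame from \code{\link{fisher_enrichment}}.
#' @param threshold strict upper bound on p_adj (default 0.25).
#' @return the rows with p_adj < threshold, sorted.
#' @export
select_enriched <- function(results, threshold = 0.25) {
  out <- results[results$p_adj < threshold, , drop = FALSE]
  out[order(out$p_adj, out$p), , drop = FALSE]
}
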