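#' End-to-end pipeline
#'
#' Orchestrates gene scoring, network construction, module search, module
#' evaluation, the connectivity test and enrichment from a single
#' configuration with deterministic seeding. Stage outputs are pure
#' functions of (inputs, config, seed); per-stage seeds are derived from
#' the master seed and the stage name.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' Defaults reproduce the analysis settings: a 20 kb gene flank, edges
#' supported by >= 2 publications, the 0.05 sigMHC threshold, dense module
#' search at r = 0.1 / d = 1, 10,000 permutations for both permutation
#' tests, 0.05 per-stage module thresholds, and a 0.25 BH threshold for
#' enrichment.
#'
#' @param association_file,gene_model_file,interaction_file input paths.
#' @param genotype_file optional dosage matrix path (identity LD if NULL).
#' @param gmt_file optional gene-set file; enrichment is skipped if NULL.
#' @param out_dir output directory; NULL disables file output.
#' @param flank,min_pubs,alpha_mhc,r,d,n_perm_topo,n_perm_conn,alpha_module,enrichment_threshold
#'   analysis parameters (see module documentation).
#' @param mhc MHC region, list(chrom, start, end).
#' @param stages,escalate_below gene-test Monte Carlo schedule.
#' @param seed master integer seed.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(association_file = NULL, gene_model_file = NULL,
                            interaction_file = NULL, genotype_file = NULL,
                            gmt_file = NULL, out_dir = NULL,
                            flank = 20000L, min_pubs = 2L,
                            alpha_mhc = 0.05, r = 0.1, d = 1L,
                            n_perm_topo = 10000L, n_perm_conn = 10000L,
                            alpha_module = 0.05,
                            enrichment_threshold = 0.25,
                            mhc = mhc_region_default(),
                            stages = c(1e3, 1e4, 1e6),
                            escalate_below = c(0.1, 0.005), seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Validate pipeline inputs without running anything
#'
#' Checks file existence and headers, and the id-namespace overlap between
#' scored genes and network nodes (a warning below 50%). Never mutates
#' inputs.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return data.frame with columns level ("fatal"/"warning") and message;
#'   zero rows when everything checks out.
#' @export
validate_inputs <- function(config) {
  issues <- list()
  add <- function(level, msg)
    issues[[length(issues) + 1]] <<- data.frame(
      level = level, message = msg, stringsAsFactors = FALSE)
  need <- c(association = config$association_file,
            gene_models = config$gene_model_file,
            interactions = config$interaction_file)
  for (nm in names(need)) {
    if (is.null(need[[nm]]) || !file.exists(need[[nm]])) {
      add("fatal", paste0("missing ", nm, " file: ",
                          if (is.null(need[[nm]])) "(unset)"
                          else need[[nm]]))
    }
  }
  if (!is.null(config$genotype_file) &&
      !file.exists(config$genotype_file))
    add("fatal", paste0("missing genotype file: ", config$genotype_file))
  if (length(issues) == 0) {
    snps <- tryCatch(read_associations(config$association_file),
                     error = function(e) {
                       add("fatal", conditionMessage(e)); NULL
                     })
    genes <- tryCatch(read_gene_models(config$gene_model_file),
                      error = function(e) {
                        add("fatal", conditionMessage(e)); NULL
                      })
    rec <- tryCatch(parse_interactions(config$interaction_file),
                    error = function(e) {
                      add("fatal", conditionMessage(e)); NULL
                    })
    if (!is.null(genes) && !is.null(rec)) {
      net_ids <- unique(c(rec$protein_a, rec$protein_b))
      ov <- mean(net_ids %in% genes$gene_id)
      if (ov < 0.5)
        add("warning", sprintf(
          "only %.0f%% of network nodes have a gene model", 100 * ov))
    }
  }
  if (length(issues) == 0)
    return(data.frame(level = character(), message = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, issues)
}

#' Module-discovery stages on an annotated network
#'
#' Runs search, two-stage evaluation and the merge on an already annotated
#' network; used both by \code{\link{run_all}} and directly when gene
#' P-values come from a synthetic dataset.
#'
#' @param annotated list from \code{\link{annotate_weights}}.
#' @param r,d,n_perm_topo,alpha_module analysis parameters.
#' @param seed master integer seed.
#' @return list: modules, evaluated, merged (see
#'   \code{\link{select_and_merge}}).
#' @export
run_module_stages <- function(annotated, r = 0.1, d = 1L,
                              n_perm_topo = 10000L, alpha_module = 0.05,
                              seed = 1L) {
  params <- search_params(r = r, d = d,
                          exclude_seeds = annotated$sig_mhc_genes)
  modules <- search_all(annotated$network, params)
  evaluated <- evaluate_modules(modules, annotated$network,
                                n_perm = n_perm_topo, alpha = alpha_module,
                                seed = derive_seed(seed, "module_eval"))
  merged <- select_and_merge(evaluated, annotated$network,
                             annotated$sig_mhc_genes)
  list(modules = modules, evaluated = evaluated, merged = merged)
}

#' Run the full pipeline
#'
#' gene scoring -> network building -> module search -> module evaluation
#' -> connectivity test -> enrichment. Writes per-stage TSVs plus a
#' resolved-config record when \code{out_dir} is set.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return list of class \code{pipeline_report}: per-stage results and a
#'   \code{counts} list (genes_scored, network nodes/edges, sigMHC count,
#'   modules found / after stage 1 / final, candidate gene total).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  val <- validate_inputs(config)
  if (any(val$level == "fatal"))
    stop("input validation failed: ",
         paste(val$message[val$level == "fatal"], collapse = "; "),
         call. = FALSE)

  snps <- read_associations(config$association_file)
  gene_models <- read_gene_models(config$gene_model_file)
  genotypes <- if (!is.null(config$genotype_file))
    read_genotypes(config$genotype_file) else NULL

  scores <- score_all_genes(snps, gene_models, genotypes,
                            flank = config$flank, stages = config$stages,
                            escalate_below = config$escalate_below,
                            seed = derive_seed(config$seed, "gene_scoring"))

  records <- parse_interactions(config$interaction_file)
  ppi <- filter_edges(records, config$min_pubs)
  annotated <- annotate_weights(ppi, scores, gene_models,
                                mhc = config$mhc,
                                alpha_mhc = config$alpha_mhc)

  stages_out <- run_module_stages(annotated, r = config$r, d = config$d,
                                  n_perm_topo = config$n_perm_topo,
                                  alpha_module = config$alpha_module,
                                  seed = config$seed)
  merged <- stages_out$merged

  connectivity <- NULL
  if (length(merged$module_gene_union) >= 2)
    connectivity <- connectivity_pvalue(
      annotated$network, merged$module_gene_union,
      n_perm = config$n_perm_conn,
      seed = derive_seed(config$seed, "connectivity"))

  enrich <- NULL
  if (!is.null(config$gmt_file) &&
      length(merged$module_gene_union) > 0) {
    collection <- read_gmt(config$gmt_file)
    background <- igraph::V(annotated$network)$name[
      igraph::V(annotated$network)$weighted]
    enrich <- fisher_enrichment(merged$module_gene_union, collection,
                                background)
    enrich <- list(all = enrich,
                   selected = select_enriched(
                     enrich, config$enrichment_threshold))
  }

  ev <- stages_out$evaluated
  counts <- list(
    snps_read = nrow(snps),
    genes_scored = nrow(scores),
    network_nodes = igraph::vcount(annotated$network),
    network_edges = igraph::ecount(annotated$network),
    sig_mhc = length(annotated$sig_mhc_genes),
    modules_found = nrow(stages_out$modules),
    modules_stage1 = sum(ev$p_norm < config$alpha_module),
    modules_final = merged$n_modules,
    module_genes = length(merged$module_gene_union),
    candidate_genes = length(merged$candidate_genes))

  report <- structure(
    list(config = config, validation = val, gene_scores = scores,
         annotated = annotated, modules = stages_out$modules,
         evaluated = ev, merged = merged, connectivity = connectivity,
         enrichment = enrich, counts = counts),
    class = "pipeline_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# Persist intermediates as headed TSVs plus the resolved configuration.
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) utils::write.table(
    df, file.path(out_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)
  wr(report$gene_scores, "gene_scores.tsv")
  wr(report$modules, "modules.tsv")
  ev <- report$evaluated
  ev$PASS <- ev$pass
  wr(ev[, c("seed", "k", "score", "p_norm", "p_topo", "PASS", "genes")],
     "modules_evaluated.tsv")
  writeLines(report$merged$candidate_genes,
             file.path(out_dir, "candidate_genes.txt"))
  write_edge_list(report$merged$extended,
                  file.path(out_dir, "candidate_subnetwork.tsv"))
  write_graphml(strip_na_attrs(report$merged$extended),
                file.path(out_dir, "candidate_subnetwork.graphml"))
  if (!is.null(report$connectivity)) {
    cn <- report$connectivity
    writeLines(c(sprintf("observed\t%d", cn$observed_edges),
                 sprintf("n_perm\t%d", cn$n_perm),
                 sprintf("p_value\t%.8g", cn$p_value)),
               file.path(out_dir, "connectivity.tsv"))
  }
  if (!is.null(report$enrichment))
    wr(report$enrichment$all, "enrichment.tsv")
  cfg <- report$config
  cfg$mhc <- sprintf("%s:%d-%d", cfg$mhc$chrom, cfg$mhc$start, cfg$mhc$end)
  flat <- vapply(cfg, function(x)
    if (is.null(x)) "NULL" else paste(format(x), collapse = ","),
    character(1))
  writeLines(paste(names(flat), flat, sep = "\t"),
             file.path(out_dir, "config_resolved.tsv"))
  invisible(out_dir)
}

# GraphML cannot carry NA numeric attributes portably; blank them.
strip_na_attrs <- function(g) {
  for (a in igraph::vertex_attr_names(g)) {
    v <- igraph::vertex_attr(g, a)
    if (is.numeric(v) && anyNA(v))
      g <- igraph::set_vertex_attr(g, a, value = ifelse(is.na(v), -999, v))
  }
  g
}

#' @export
print.pipeline_report <- function(x, ...) {
  c <- x$counts
  cat("network-assisted GWAS pipeline report\n")
  cat(sprintf("  genes scored:        %d\n", c$genes_scored))
  cat(sprintf("  weighted network:    %d nodes / %d edges\n",
              c$network_nodes, c$network_edges))
  cat(sprintf("  sigMHC-genes:        %d\n", c$sig_mhc))
  cat(sprintf("  modules: %d found -> %d after score test -> %d final\n",
              c$modules_found, c$modules_stage1, c$modules_final))
  cat(sprintf("  module genes:        %d\n", c$module_genes))
  cat(sprintf("  candidate genes:     %d\n", c$candidate_genes))
  if (!is.null(x$connectivity))
    cat(sprintf("  connectivity: %d direct edges, p = %.3g (%d perms)\n",
                x$connectivity$observed_edges, x$connectivity$p_value,
                x$connectivity$n_perm))
  invisible(x)
}
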