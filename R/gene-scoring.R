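#' Gene-level association scoring
#'
#' Combines SNP-level association P-values into one gene-level P-value while
#' modeling linkage disequilibrium (LD) between the SNPs, following the
#' VEGAS approach: the gene statistic is the sum of upper-tail 1-df
#' chi-square quantiles of the SNP P-values, and its null distribution is
#' obtained by Monte Carlo simulation from a multivariate normal whose
#' covariance is the SNP correlation (LD) matrix estimated from a reference
#' genotype panel.
#'
#' @name gene_scoring
NULL

# SNP p-values below this floor are clamped before the chi-square quantile
# transform to avoid infinite statistics.
P_FLOOR <- 1e-16

#' Read a SNP association table
#'
#' Tab-delimited with header \code{SNP CHR POS P} (a PLINK .assoc-compatible
#' subset). Only autosomes (1-22, with or without a "chr" prefix) are
#' retained; other chromosome labels are dropped with a warning.
#'
#' @param path file path.
#' @return data.frame with columns snp_id, chrom, pos, p_value.
#' @export
read_associations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("SNP", "CHR", "POS", "P")
  if (!all(need %in% names(df)))
    stop("association table must have header SNP CHR POS P: ", path,
         call. = FALSE)
  out <- data.frame(snp_id = as.character(df$SNP),
                    chrom = sub("^chr", "", as.character(df$CHR)),
                    pos = as.integer(df$POS), p_value = as.numeric(df$P),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$snp_id))
    stop("duplicate SNP ids in ", path, call. = FALSE)
  keep <- out$chrom %in% as.character(1:22)
  if (any(!keep))
    warning(sum(!keep), " SNP(s) on non-autosomal/unknown chromosomes ",
            "dropped")
  out <- out[keep, , drop = FALSE]
  bad <- !is.finite(out$p_value) | out$p_value <= 0 | out$p_value > 1
  if (any(bad)) stop("P-values must lie in (0, 1]", call. = FALSE)
  out
}

#' Read gene models
#'
#' Either a TSV with header \code{GENE CHR START END} (1-based, fully closed
#' intervals) or a BED file (extension \code{.bed}, 0-based half-open,
#' converted to 1-based closed on read).
#'
#' @param path file path.
#' @return data.frame with columns gene_id, chrom, start, end.
#' @export
read_gene_models <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    out <- data.frame(gene_id = as.character(df[[4]]),
                      chrom = sub("^chr", "", as.character(df[[1]])),
                      start = as.integer(df[[2]]) + 1L,
                      end = as.integer(df[[3]]), stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("GENE", "CHR", "START", "END")
    if (!all(need %in% names(df)))
      stop("gene model table must have header GENE CHR START END: ", path,
           call. = FALSE)
    out <- data.frame(gene_id = as.character(df$GENE),
                      chrom = sub("^chr", "", as.character(df$CHR)),
                      start = as.integer(df$START), end = as.integer(df$END),
                      stringsAsFactors = FALSE)
  }
  if (any(out$start > out$end)) stop("gene start > end", call. = FALSE)
  out
}

#' Read a genotype dosage matrix
#'
#' Tab-delimited, rows = SNPs (first column the SNP id), columns = samples;
#' dosages 0/1/2 or fractional.
#'
#' @param path file path.
#' @return numeric matrix with SNP ids as rownames.
#' @export
read_genotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  g <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(g) <- "double"
  rownames(g) <- as.character(df[[1]])
  g
}

#' Map SNPs to genes by position with a flank
#'
#' A SNP maps to a gene when its position lies in the closed window
#' [start - flank, end + flank] on the same chromosome. A SNP may map to
#' several genes; genes capturing no SNP are omitted.
#'
#' @param snps data.frame as from \code{\link{read_associations}}.
#' @param genes data.frame as from \code{\link{read_gene_models}}.
#' @param flank window extension in base pairs (default 20 kb, applied both
#'   upstream and downstream).
#' @return named list: gene id -> data.frame of that gene's SNP rows.
#' @export
map_snps_to_genes <- function(snps, genes, flank = 20000L) {
  stopifnot(flank >= 0)
  if (anyDuplicated(snps$snp_id)) stop("duplicate SNP ids", call. = FALSE)
  known <- snps$chrom %in% as.character(1:22)
  if (any(!known)) {
    warning(sum(!known), " SNP(s) with unknown chromosome labels skipped")
    snps <- snps[known, , drop = FALSE]
  }
  by_chr <- split(snps, snps$chrom)
  out <- vector("list", nrow(genes))
  names(out) <- genes$gene_id
  for (i in seq_len(nrow(genes))) {
    s <- by_chr[[genes$chrom[i]]]
    if (is.null(s)) next
    hit <- s$pos >= genes$start[i] - flank & s$pos <= genes$end[i] + flank
    if (any(hit)) out[[i]] <- s[hit, , drop = FALSE]
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Gene test statistic: sum of 1-df chi-square quantiles
#'
#' For SNP P-values p_1..p_m the statistic is the sum over SNPs of the
#' upper-tail chi-square(1) quantile of p_j; additive over SNPs, zero when
#' every p_j = 1.
#'
#' @param snp_pvalues numeric vector of P-values in (0, 1].
#' @return non-negative scalar.
#' @export
gene_statistic <- function(snp_pvalues) {
  if (length(snp_pvalues) == 0) stop("gene has no SNPs", call. = FALSE)
  if (any(snp_pvalues <= 0 | snp_pvalues > 1))
    stop("SNP P-values must lie in (0, 1]", call. = FALSE)
  sum(stats::qchisq(pmax(snp_pvalues, P_FLOOR), df = 1,
                    lower.tail = FALSE))
}

#' LD matrix from a dosage panel
#'
#' Pairwise Pearson correlation of SNP dosages, repaired to the nearest
#' positive semi-definite correlation matrix when the sample estimate is
#' indefinite or singular: eigenvalues below a small epsilon are clipped and
#' the matrix is rescaled to unit diagonal.
#'
#' @param genotypes numeric matrix, rows = SNPs (rownames = SNP ids),
#'   columns = samples (>= 2).
#' @return list of class \code{ld_matrix} with \code{snp_ids} and
#'   \code{matrix}.
#' @export
ld_correlation <- function(genotypes) {
  stopifnot(is.matrix(genotypes), ncol(genotypes) >= 2)
  ids <- rownames(genotypes)
  if (is.null(ids)) ids <- sprintf("snp%d", seq_len(nrow(genotypes)))
  all_na <- apply(genotypes, 1, function(x) all(is.na(x)))
  if (any(all_na))
    stop("SNP(s) with all-missing dosages: ",
         paste(ids[all_na], collapse = ", "), call. = FALSE)
  sds <- apply(genotypes, 1, stats::sd, na.rm = TRUE)
  mono <- sds == 0
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP(s) dropped from LD: ",
            paste(ids[mono], collapse = ", "))
    genotypes <- genotypes[!mono, , drop = FALSE]
    ids <- ids[!mono]
  }
  if (nrow(genotypes) == 0) stop("no polymorphic SNPs left", call. = FALSE)
  r <- stats::cor(t(genotypes), use = "pairwise.complete.obs")
  r <- repair_psd(r)
  dimnames(r) <- list(ids, ids)
  structure(list(snp_ids = ids, matrix = r), class = "ld_matrix")
}

# Clip eigenvalues below eps and rescale to a unit-diagonal correlation
# matrix; sample correlations from finite panels are often indefinite.
repair_psd <- function(r, eps = 1e-10) {
  r <- (r + t(r)) / 2
  ev <- eigen(r, symmetric = TRUE)
  if (all(ev$values > eps)) {
    diag(r) <- 1
    return(r)
  }
  lam <- pmax(ev$values, eps)
  r2 <- ev$vectors %*% (lam * t(ev$vectors))
  r2 <- stats::cov2cor(r2)
  (r2 + t(r2)) / 2
}

#' Monte Carlo gene P-value under the LD-aware null
#'
#' Draws vectors from a zero-mean multivariate normal with covariance equal
#' to the LD matrix, sums the squared components of each draw, and returns
#' the empirical upper-tail probability of the observed statistic with the
#' (+1)/(+1) correction. An adaptive schedule escalates the number of draws
#' when the P-value estimate is small, so modest genes are cheap and
#' significant genes get precision.
#'
#' @param statistic observed gene statistic.
#' @param ld an \code{\link{ld_correlation}} result (or a plain correlation
#'   matrix).
#' @param stages increasing vector of simulation sizes; stage s+1 runs when
#'   the current estimate is below \code{escalate_below[s]}.
#' @param escalate_below thresholds driving escalation (one fewer than
#'   stages).
#' @param seed integer seed.
#' @return list with \code{p_value} and \code{n_sims_used}.
#' @export
gene_pvalue <- function(statistic, ld, stages = c(1e3, 1e4, 1e6),
                        escalate_below = c(0.1, 0.005), seed = 1L) {
  stopifnot(statistic >= 0, length(stages) >= 1,
            length(escalate_below) == length(stages) - 1)
  r <- if (inherits(ld, "ld_matrix")) ld$matrix else as.matrix(ld)
  k <- nrow(r)
  ch <- tryCatch(chol(r), error = function(e) {
    r2 <- repair_psd(r)
    tryCatch(chol(r2 + diag(1e-8, k)), error = function(e2)
      stop("LD matrix is not positive semi-definite after repair",
           call. = FALSE))
  })
  with_seed(seed, {
    p <- NA_real_
    n_used <- 0
    for (s in seq_along(stages)) {
      n <- as.integer(stages[s])
      sums <- simulate_null_sums(ch, n)
      p <- empirical_pvalue(sum(sums >= statistic), n)
      n_used <- n
      if (s < length(stages) && p >= escalate_below[s]) break
    }
    list(p_value = p, n_sims_used = n_used)
  })
}

# Null statistics: rows of Z %*% chol(R) have covariance R; blockwise to
# bound memory at large simulation sizes.
simulate_null_sums <- function(ch, n) {
  k <- ncol(ch)
  block <- 200000L
  out <- numeric(n)
  done <- 0L
  while (done < n) {
    nb <- min(block, n - done)
    z <- matrix(stats::rnorm(nb * k), nrow = nb) %*% ch
    out[(done + 1L):(done + nb)] <- rowSums(z * z)
    done <- done + nb
  }
  out
}

#' Draws from the null distribution of the gene statistic
#'
#' Exposed for calibration checks: with identity LD the sums are exactly
#' chi-square with as many degrees of freedom as SNPs.
#'
#' @param ld correlation matrix or \code{ld_matrix}.
#' @param n number of draws.
#' @param seed integer seed.
#' @return numeric vector of simulated null statistics.
#' @export
simulate_null_statistics <- function(ld, n, seed = 1L) {
  r <- if (inherits(ld, "ld_matrix")) ld$matrix else as.matrix(ld)
  with_seed(seed, simulate_null_sums(chol(r), as.integer(n)))
}

#' Score all genes
#'
#' Maps SNPs to genes, estimates each gene's LD matrix from the genotype
#' panel (identity LD when no panel is supplied, e.g. for single-SNP genes),
#' and computes the Monte Carlo gene P-value. Per-gene seeds are derived
#' from the master seed and the gene id, so results do not depend on
#' evaluation order.
#'
#' @param snps association data.frame (snp_id, chrom, pos, p_value).
#' @param genes gene model data.frame (gene_id, chrom, start, end).
#' @param genotypes optional dosage matrix with SNP ids as rownames; SNPs
#'   absent from the panel fall back to identity LD with a warning.
#' @param flank mapping window in bp (default 20 kb).
#' @param stages,escalate_below see \code{\link{gene_pvalue}}.
#' @param seed master integer seed.
#' @return data.frame: gene_id, n_snps, statistic, p_value, n_sims_used (one
#'   row per gene with at least one mapped SNP).
#' @export
score_all_genes <- function(snps, genes, genotypes = NULL, flank = 20000L,
                            stages = c(1e3, 1e4, 1e6),
                            escalate_below = c(0.1, 0.005), seed = 1L) {
  mapped <- map_snps_to_genes(snps, genes, flank)
  res <- lapply(names(mapped), function(gid) {
    s <- mapped[[gid]]
    pv <- s$p_value
    ld <- NULL
    if (!is.null(genotypes)) {
      have <- s$snp_id %in% rownames(genotypes)
      if (!all(have)) {
        warning("gene ", gid, ": ", sum(!have),
                " SNP(s) missing from genotype panel; identity LD used ",
                "for the gene")
      } else if (length(pv) > 1) {
        ld <- tryCatch(ld_correlation(genotypes[s$snp_id, , drop = FALSE]),
                       error = function(e)
                         stop("gene ", gid, ": ", conditionMessage(e),
                              call. = FALSE))
        keep <- s$snp_id %in% ld$snp_ids # monomorphic SNPs dropped
        pv <- pv[keep]
        if (length(pv) == 0) return(NULL)
      }
    }
    if (is.null(ld)) ld <- diag(length(pv))
    stat <- gene_statistic(pv)
    mc <- gene_pvalue(stat, ld, stages, escalate_below,
                      seed = derive_seed(seed, gid))
    data.frame(gene_id = gid, n_snps = length(pv), statistic = stat,
               p_value = mc$p_value, n_sims_used = mc$n_sims_used,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(gene_id = character(), n_snps = integer(),
                      statistic = numeric(), p_value = numeric(),
                      n_sims_used = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
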