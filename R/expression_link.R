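#' Compute RPKM from read counts
#'
#' Reads per kilobase of gene model per million mapped reads:
#' \code{count / (length_kb x mapped_millions)}.
#'
#' @param counts Sample-by-gene matrix of read counts.
#' @param gene_lengths Named (or column-aligned) gene lengths in bases.
#' @param library_sizes Named (or row-aligned) mapped-read totals per sample.
#' @return Sample-by-gene RPKM matrix.
#' @export
compute_rpkm <- function(counts, gene_lengths, library_sizes) {
  counts <- as.matrix(counts)
  if (length(gene_lengths) != ncol(counts))
    stop("gene_lengths must match the number of genes (columns)")
  if (length(library_sizes) != nrow(counts))
    stop("library_sizes must match the number of samples (rows)")
  stopifnot(all(gene_lengths > 0), all(library_sizes > 0))
  rpkm <- counts / (rep(library_sizes / 1e6, ncol(counts)) *
                    rep(gene_lengths / 1e3, each = nrow(counts)))
  dimnames(rpkm) <- dimnames(counts)
  rpkm
}

#' Read an expression matrix from TSV
#'
#' Accepts genes-by-samples or samples-by-genes layouts; the orientation is
#' detected from the first header field (\code{gene}/\code{symbol} versus
#' \code{sample}). Returns a sample-by-gene matrix.
#'
#' @param path Path to a tab-separated matrix with a leading identifier
#'   column.
#' @return Numeric matrix, samples in rows, genes in columns.
#' @export
read_expression <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  idcol <- tolower(names(tab)[1])
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  if (grepl("gene|symbol", idcol)) m <- t(m)
  storage.mode(m) <- "double"
  m
}

#' Normalized expression fold change between mutated and unmutated samples
#'
#' Partitions the cohort by the presence of at least one somatic SNV in the
#' gene's SHM-target and reports \code{(mean_mut - mean_unmut) /
#' (mean_mut + mean_unmut)}, a symmetric measure bounded in [-1, 1]. The
#' fold change is set to zero for genes with low expression in both groups
#' (both means below \code{min_rpkm}), or when either group is empty.
#'
#' @param expr Sample-by-gene RPKM matrix.
#' @param gene Gene symbol (must be a column of \code{expr}).
#' @param mutated_samples Character vector of mutated sample ids.
#' @param min_rpkm Low-expression floor (default 5).
#' @return List with \code{gene_symbol}, \code{mean_rpkm_mutated},
#'   \code{mean_rpkm_unmutated}, \code{fold_change}.
#' @export
expression_fold_change <- function(expr, gene, mutated_samples, min_rpkm = 5) {
  if (!gene %in% colnames(expr)) stop("gene absent from expression matrix: ", gene)
  x <- expr[, gene]
  mut <- intersect(rownames(expr), mutated_samples)
  unmut <- setdiff(rownames(expr), mut)
  m_mut <- if (length(mut)) mean(x[mut]) else NA_real_
  m_un <- if (length(unmut)) mean(x[unmut]) else NA_real_
  fc <- if (is.na(m_mut) || is.na(m_un) || (m_mut + m_un) == 0) 0
        else if (m_mut < min_rpkm && m_un < min_rpkm) 0
        else (m_mut - m_un) / (m_mut + m_un)
  list(gene_symbol = gene, mean_rpkm_mutated = m_mut,
       mean_rpkm_unmutated = m_un, fold_change = fc)
}

#' Expression linkage for a set of genes
#'
#' Vectorized [expression_fold_change()] over a gene-to-mutated-samples map.
#'
#' @param expr Sample-by-gene RPKM matrix.
#' @param mutated_sample_map Named list: gene symbol -> character vector of
#'   mutated sample ids.
#' @param min_rpkm Low-expression floor (default 5).
#' @return Data.frame with one row per gene.
#' @export
expression_link_table <- function(expr, mutated_sample_map, min_rpkm = 5) {
  genes <- intersect(names(mutated_sample_map), colnames(expr))
  rows <- lapply(genes, function(g)
    as.data.frame(expression_fold_change(expr, g, mutated_sample_map[[g]],
                                         min_rpkm)))
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_symbol = character(), mean_rpkm_mutated = numeric(),
                      mean_rpkm_unmutated = numeric(), fold_change = numeric())
  out
}

#' Random-gene-set resampling test of candidate-set expression
#'
#' Draws \code{n_draws} random gene sets of the candidate-set size, without
#' replacement, from the expressed universe (genes with mean RPKM above
#' \code{min_rpkm_universe}) and compares the candidate-set mean RPKM with
#' the empirical null of random-set means (one-sided, greater). A plain
#' two-sample Welch test of candidate gene means against universe gene means
#' is available as an alternative.
#'
#' @param candidate_genes Character vector of gene symbols.
#' @param expr Sample-by-gene RPKM matrix.
#' @param min_rpkm_universe Universe expression floor (default 1).
#' @param n_draws Number of random sets (default 1000); fewer than 20 draws
#'   is flagged as a degenerate null.
#' @param seed Integer seed for the draws.
#' @param method \code{"empirical"} (default) or \code{"t_test"}.
#' @return List with \code{candidate_mean}, \code{null_means},
#'   \code{effect_size}, \code{p}, \code{degenerate}.
#' @export
random_set_expression_test <- function(candidate_genes, expr,
                                       min_rpkm_universe = 1, n_draws = 1000,
                                       seed = 1,
                                       method = c("empirical", "t_test")) {
  method <- match.arg(method)
  gene_means <- colMeans(expr)
  universe <- names(gene_means)[gene_means > min_rpkm_universe]
  cand <- intersect(candidate_genes, colnames(expr))
  k <- length(cand)
  if (k == 0) stop("no candidate gene present in the expression matrix")
  if (length(universe) <= k)
    stop("expressed universe (", length(universe),
         ") is not larger than the candidate set (", k, ")")
  cand_mean <- mean(gene_means[cand])
  if (method == "t_test") {
    tt <- stats::t.test(gene_means[cand], gene_means[universe],
                        alternative = "greater")
    return(list(candidate_mean = cand_mean, null_means = gene_means[universe],
                effect_size = cand_mean - mean(gene_means[universe]),
                p = tt$p.value, degenerate = FALSE))
  }
  null_means <- with_seed(seed, vapply(seq_len(n_draws), function(i)
    mean(gene_means[sample(universe, k)]), numeric(1)))
  p <- (1 + sum(null_means >= cand_mean)) / (n_draws + 1)
  list(candidate_mean = cand_mean, null_means = null_means,
       effect_size = cand_mean - mean(null_means), p = p,
       degenerate = n_draws < 20)
}
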