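#' Gene-set overlap enrichment (hypergeometric upper tail)
#'
#' Probability of observing at least the candidate/set overlap when
#' candidates are drawn uniformly from the universe. Candidates or set
#' members outside the universe are dropped with a warning.
#'
#' @param candidates,gene_set,universe Character vectors of gene symbols.
#' @return List with \code{n_candidates}, \code{n_set}, \code{n_universe},
#'   \code{n_overlap}, \code{p}.
#' @export
gene_set_overlap_test <- function(candidates, gene_set, universe) {
  universe <- unique(universe)
  drop_c <- setdiff(candidates, universe)
  drop_s <- setdiff(gene_set, universe)
  if (length(drop_c)) warning(length(drop_c), " candidate(s) outside the universe dropped")
  if (length(drop_s)) warning(length(drop_s), " gene-set member(s) outside the universe dropped")
  candidates <- unique(intersect(candidates, universe))
  gene_set <- unique(intersect(gene_set, universe))
  k <- length(intersect(candidates, gene_set))
  list(n_candidates = length(candidates), n_set = length(gene_set),
       n_universe = length(universe), n_overlap = k,
       p = hyper_upper_tail(k, length(gene_set), length(candidates),
                            length(universe)))
}

#' Per-gene association between mutation status and molecular subtype
#'
#' Builds, for each gene, the 2x2 table of mutated/unmutated samples by
#' subtype (samples with unknown subtype excluded) and reports the exact
#' test: two-sided, and one-sided for mutation excess in the first subtype
#' level (GCB by default). Benjamini-Hochberg adjustment across genes is
#' applied to the two-sided p-values.
#'
#' @param mutated_map Named list: gene -> character vector of mutated
#'   sample ids.
#' @param subtypes Named character vector sample -> subtype label.
#' @param levels The two subtype labels, first level = tested direction
#'   (default \code{c("GCB", "ABC")}).
#' @param adjust Apply BH adjustment across genes (default \code{TRUE}).
#' @return Data.frame with per-gene counts, \code{p_one_sided},
#'   \code{p_two_sided}, and \code{q_two_sided}.
#' @export
subtype_association <- function(mutated_map, subtypes,
                                levels = c("GCB", "ABC"), adjust = TRUE) {
  known <- names(subtypes)[subtypes %in% levels]
  rows <- lapply(names(mutated_map), function(g) {
    mut <- intersect(mutated_map[[g]], known)
    m1 <- sum(subtypes[mut] == levels[1])
    m2 <- sum(subtypes[mut] == levels[2])
    n1 <- sum(subtypes[known] == levels[1]) - m1
    n2 <- sum(subtypes[known] == levels[2]) - m2
    tab <- matrix(c(m1, n1, m2, n2), nrow = 2)
    if (sum(tab[1, ]) == 0) {
      p1 <- p2 <- 1
    } else {
      p1 <- fisher.test(tab, alternative = "greater")$p.value
      p2 <- fisher.test(tab)$p.value
    }
    data.frame(gene_symbol = g,
               mutated_1 = m1, unmutated_1 = n1,
               mutated_2 = m2, unmutated_2 = n2,
               p_one_sided = p1, p_two_sided = p2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:5] <- c(paste0("mutated_", levels[1]), paste0("unmutated_", levels[1]),
                       paste0("mutated_", levels[2]), paste0("unmutated_", levels[2]))
  if (adjust && nrow(out)) out$q_two_sided <- benjamini_adjust(out$p_two_sided)
  out
}
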