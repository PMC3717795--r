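#' Stratify SHM-targets into mutation-rate groups
#'
#' Group I holds targets whose cohort mutation density exceeds
#' \code{high_threshold}, group II those above \code{mid_threshold}, and
#' group III the remaining targets with at least \code{min_snvs} distinct
#' SNVs; everything else is unassigned. Genes on the immunoglobulin-locus
#' list are always assigned to the positive-control group regardless of
#' density. \code{mode = "snv_count"} instead defines group II by an SNV
#' count range (default 3--5).
#'
#' @param features Table from [build_feature_table()] (needs
#'   \code{mutation_density} and \code{total_snvs}).
#' @param high_threshold,mid_threshold Density cutoffs (defaults 8e-5 and
#'   4e-5 events per base per sample).
#' @param ig_genes Character vector of immunoglobulin-locus gene symbols.
#' @param min_snvs Minimum distinct SNVs for group III (default 2).
#' @param mode \code{"density"} (default) or \code{"snv_count"}.
#' @param snv_range Group-II SNV count range for \code{mode = "snv_count"}.
#' @return Data.frame with columns \code{gene_symbol}, \code{group},
#'   \code{mutation_density}, \code{n_snvs_total}.
#' @export
assign_groups <- function(features, high_threshold = 8e-5, mid_threshold = 4e-5,
                          ig_genes = character(), min_snvs = 2,
                          mode = c("density", "snv_count"),
                          snv_range = c(3, 5)) {
  mode <- match.arg(mode)
  stopifnot(high_threshold > mid_threshold, mid_threshold > 0)
  d <- features$mutation_density
  n <- features$total_snvs
  group <- rep("unassigned", nrow(features))
  if (mode == "density") {
    group[n >= min_snvs] <- "III"
    group[d > mid_threshold] <- "II"
    group[d > high_threshold] <- "I"
  } else {
    group[n >= min_snvs] <- "III"
    group[n >= snv_range[1] & n <= snv_range[2]] <- "II"
    group[d > high_threshold] <- "I"
  }
  group[n < min_snvs & group != "I" & group != "II"] <- "unassigned"
  group[features$gene %in% ig_genes] <- "IG_control"
  data.frame(gene_symbol = features$gene, group = group,
             mutation_density = d, n_snvs_total = n,
             stringsAsFactors = FALSE)
}

#' Distance-to-TSS profiles of somatic SNVs per group
#'
#' Pools, over the genes of each group, the SNV offsets from the TSS in the
#' transcription direction within a profile window (default 12 kb, wider
#' than the 2-kb analysis window, for visualising how far the mutation mass
#' extends into the gene body). Reports the pooled distances, their median,
#' and a local-regression smooth of the binned histogram. Smoothing is for
#' display only and never feeds the statistics.
#'
#' @param snvs Somatic SNVs from [filter_somatic()].
#' @param targets Table from [derive_shm_targets()] (carries strand and TSS).
#' @param groups Assignment table from [assign_groups()]; when \code{NULL}
#'   all genes form a single \code{"all"} group.
#' @param profile_window Profile extent downstream of the TSS in bases.
#' @param bin_bp Histogram bin width in bases (default 250).
#' @param span Local-regression span (default 0.3).
#' @return Named list of profiles, each a list with \code{group},
#'   \code{distances}, \code{median_distance}, \code{smoothed_density}.
#' @export
tss_distance_profile <- function(snvs, targets, groups = NULL,
                                 profile_window = 12000, bin_bp = 250,
                                 span = 0.3) {
  if (is.null(groups))
    groups <- data.frame(gene_symbol = targets$gene_symbol, group = "all",
                         stringsAsFactors = FALSE)
  gmap <- setNames(groups$group, groups$gene_symbol)
  dist_by_group <- list()
  for (i in seq_len(nrow(targets))) {
    tg <- targets[i, ]
    grp <- unname(gmap[tg$gene_symbol])
    if (is.na(grp)) next
    on_chr <- snvs[snvs$chrom == tg$chrom, , drop = FALSE]
    d <- if (tg$strand == "+") on_chr$pos - tg$tss else tg$tss - on_chr$pos
    d <- d[d >= 0 & d <= profile_window]
    dist_by_group[[grp]] <- c(dist_by_group[[grp]], d)
  }
  lapply(setNames(nm = names(dist_by_group)), function(grp) {
    d <- dist_by_group[[grp]]
    smoothed <- smooth_distance_density(d, profile_window, bin_bp, span)
    list(group = grp, distances = d,
         median_distance = if (length(d)) median(d) else NA_real_,
         smoothed_density = smoothed)
  })
}

smooth_distance_density <- function(d, profile_window, bin_bp, span) {
  breaks <- seq(0, profile_window + bin_bp, by = bin_bp)
  mids <- head(breaks, -1) + bin_bp / 2
  counts <- as.integer(table(cut(d, breaks, right = FALSE,
                                 include.lowest = TRUE)))
  out <- data.frame(grid = mids, count = counts, value = NA_real_)
  if (length(d) >= 10) {
    fit <- suppressWarnings(loess(counts ~ mids, span = span, degree = 2))
    out$value <- pmax(predict(fit, mids), 0)
  }
  out
}

#' Compare two SNV distance distributions with a two-sample KS test
#'
#' Asymptotic p-value, switching to the exact small-sample computation when
#' both groups hold at most 100 distances. Ties (integer distances) are
#' expected; the tie warning from the underlying test is suppressed.
#'
#' @param a,b Profiles from [tss_distance_profile()] (or numeric vectors).
#' @return List with \code{statistic}, \code{p_value}, \code{n_a},
#'   \code{n_b}.
#' @export
compare_distance_distributions <- function(a, b) {
  da <- if (is.list(a)) a$distances else a
  db <- if (is.list(b)) b$distances else b
  if (length(da) == 0 || length(db) == 0)
    stop("cannot compare an empty distance profile")
  exact <- length(da) <= 100 && length(db) <= 100
  ks <- suppressWarnings(ks.test(da, db, exact = exact))
  list(statistic = unname(ks$statistic), p_value = ks$p.value,
       n_a = length(da), n_b = length(db))
}

#' Write per-group distance profiles as TSV
#' @param profiles List from [tss_distance_profile()].
#' @param path Output path.
#' @export
write_distance_profiles <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p)
    if (length(p$distances))
      data.frame(group = p$group, distance = p$distances,
                 stringsAsFactors = FALSE)))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
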