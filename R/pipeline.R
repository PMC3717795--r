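#' Run the full aSHM target-discovery scan
#'
#' End-to-end orchestration: load gene models and reference, derive
#' SHM-target windows, filter tumor calls to somatic SNVs, build the
#' per-gene feature table, stratify targets into mutation-rate groups,
#' profile SNV distance to the TSS with between-group KS comparisons,
#' cross-tabulate mutations with rearrangements, and (when subtype labels
#' are given) test per-gene subtype association. All reports are written to
#' \code{out_dir} alongside a JSON manifest echoing every threshold.
#'
#' Inputs may be in-memory objects (data.frames, a \code{DNAStringSet}, a
#' matrix) or file paths in the standard formats read by the package.
#'
#' @param calls Tumor variant calls: a data.frame, a directory of per-sample
#'   VCFs, or a character vector of VCF paths.
#' @param models Gene models: a data.frame from [read_gene_models()] or an
#'   annotation path.
#' @param genome Named \code{DNAStringSet} or FASTA path.
#' @param matched_normal,population Site sets: key vectors, paths, or
#'   \code{NULL}.
#' @param expr Expression: sample-by-gene matrix, TSV path, or \code{NULL}.
#' @param rearrangements Event table, path, or \code{NULL}.
#' @param subtypes Named sample-to-subtype vector, TSV path (columns
#'   \code{sample_id}, \code{subtype}), or \code{NULL}.
#' @param out_dir Output directory; \code{NULL} skips writing.
#' @param sample_ids Cohort sample universe; defaults to the samples seen in
#'   \code{calls} (supply explicitly when some samples have no calls).
#' @param window_bp SHM-target window length.
#' @param thresholds Somatic-filter thresholds from [somatic_thresholds()].
#' @param group_thresholds Density cutoffs \code{c(high, mid)}.
#' @param ig_genes Immunoglobulin-control gene list.
#' @param flank_bp Rearrangement vicinity flank.
#' @param min_rpkm Low-expression floor for fold changes.
#' @param profile_window Distance-profile extent (default 12000).
#' @param cap_at_half Cap one-sided signature p-values at 0.5.
#' @param seed Seed recorded in the manifest (the scan itself is
#'   deterministic).
#' @return List with \code{features}, \code{groups}, \code{profiles},
#'   \code{ks_tests}, \code{xtab}, \code{subtype}, \code{snvs},
#'   \code{targets}, \code{manifest}.
#' @export
run_shm_scan <- function(calls, models, genome, matched_normal = NULL,
                         population = NULL, expr = NULL,
                         rearrangements = NULL, subtypes = NULL,
                         out_dir = NULL, sample_ids = NULL, window_bp = 2000,
                         thresholds = somatic_thresholds(),
                         group_thresholds = c(high = 8e-5, mid = 4e-5),
                         ig_genes = character(), flank_bp = 1e5,
                         min_rpkm = 5, profile_window = 12000,
                         cap_at_half = TRUE, seed = 1L) {
  genome <- load_genome(genome)
  if (is.character(models)) models <- read_gene_models(models)
  calls <- load_calls(calls)
  if (is.character(matched_normal) && length(matched_normal) == 1 &&
      file.exists(matched_normal)) matched_normal <- read_site_set(matched_normal)
  if (is.character(population) && length(population) == 1 &&
      file.exists(population)) population <- read_site_set(population)
  if (is.character(expr)) expr <- read_expression(expr)
  if (is.character(rearrangements)) rearrangements <- read_rearrangements(rearrangements)
  if (is.character(subtypes) && length(subtypes) == 1 && file.exists(subtypes)) {
    st <- read.delim(subtypes, stringsAsFactors = FALSE)
    subtypes <- setNames(st$subtype, st$sample_id)
  }
  if (is.null(sample_ids)) sample_ids <- sort(unique(calls$sample_id))

  seqlen <- setNames(Biostrings::width(genome), names(genome))
  targets <- derive_shm_targets(models, window_bp, seqlengths = seqlen)
  snvs <- filter_somatic(calls, matched_normal, population, thresholds)
  features <- build_feature_table(targets, genome, snvs,
                                  n_samples = length(sample_ids),
                                  expr = expr, min_rpkm = min_rpkm,
                                  cap_at_half = cap_at_half)
  groups <- assign_groups(features, group_thresholds[["high"]],
                          group_thresholds[["mid"]], ig_genes)
  profiles <- tss_distance_profile(snvs, targets, groups,
                                   profile_window = profile_window)
  ks_tests <- group_ks_tests(profiles)

  profs <- attr(features, "profiles")
  mutated_map <- lapply(profs, `[[`, "mutated_samples")
  xtab <- NULL
  if (!is.null(rearrangements)) {
    rearr_map <- assign_events_to_genes(rearrangements, targets, flank_bp)
    xtab <- mutation_rearrangement_table(mutated_map, rearr_map, sample_ids,
                                         genes = features$gene)
  }
  subtype <- NULL
  if (!is.null(subtypes))
    subtype <- subtype_association(mutated_map[features$gene], subtypes)

  manifest <- list(
    package_version = as.character(packageVersion("ashmscan")),
    seed = seed, window_bp = window_bp, profile_window = profile_window,
    thresholds = thresholds,
    group_thresholds = as.list(group_thresholds), flank_bp = flank_bp,
    min_rpkm = min_rpkm, cap_at_half = cap_at_half,
    n_samples = length(sample_ids), n_targets = nrow(targets),
    n_somatic_snvs = nrow(snvs))
  result <- list(features = features, groups = groups, profiles = profiles,
                 ks_tests = ks_tests, xtab = xtab, subtype = subtype,
                 snvs = snvs, targets = targets, manifest = manifest)
  if (!is.null(out_dir)) write_scan_reports(result, out_dir)
  result
}

load_calls <- function(calls) {
  if (is.data.frame(calls)) return(calls)
  paths <- calls
  if (length(paths) == 1 && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.vcf(\\.gz)?$", full.names = TRUE)
  if (length(paths) == 0) stop("no VCF input found")
  do.call(rbind, lapply(sort(paths), read_variant_calls))
}

group_ks_tests <- function(profiles) {
  labs <- names(profiles)
  pairs <- if (length(labs) >= 2) utils::combn(sort(labs), 2, simplify = FALSE)
           else list()
  rows <- lapply(pairs, function(pr) {
    a <- profiles[[pr[1]]]; b <- profiles[[pr[2]]]
    if (length(a$distances) == 0 || length(b$distances) == 0) return(NULL)
    ks <- compare_distance_distributions(a, b)
    data.frame(group_a = pr[1], group_b = pr[2], ks_statistic = ks$statistic,
               p_value = ks$p_value, n_a = ks$n_a, n_b = ks$n_b,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(group_a = character(), group_b = character(),
                      ks_statistic = numeric(), p_value = numeric(),
                      n_a = integer(), n_b = integer())
  out
}

#' Write all scan reports to a directory
#'
#' Feature table (TSV rounded to 4 decimals plus full-precision JSON),
#' group assignments, per-group distance lists and medians, KS
#' comparisons, the mutation-by-rearrangement cross-tab, subtype
#' associations, the somatic SNV table, SHM-target BED, and the run
#' manifest. Files are written to a temporary name and renamed into place.
#'
#' @param result From [run_shm_scan()].
#' @param out_dir Output directory (created if absent).
#' @return \code{out_dir}, invisibly.
#' @export
write_scan_reports <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  put <- function(writer, obj, name, ...) {
    tmp <- file.path(out_dir, paste0(".tmp.", name))
    writer(obj, tmp, ...)
    file.rename(tmp, file.path(out_dir, name))
  }
  tsv <- function(obj, path) write.table(round_df(as.data.frame(obj), 4), path,
                                         sep = "\t", quote = FALSE,
                                         row.names = FALSE)
  put(tsv, result$features, "shm_features.tsv")
  put(write_json_file, as.data.frame(result$features), "shm_features.json")
  put(tsv, result$groups, "groups.tsv")
  put(write_distance_profiles, result$profiles, "tss_distances.tsv")
  put(tsv, result$ks_tests, "ks_tests.tsv")
  if (!is.null(result$xtab)) put(write_rearrangement_table, result$xtab,
                                 "mutation_rearrangement.tsv")
  if (!is.null(result$subtype)) put(tsv, result$subtype, "subtype_association.tsv")
  put(write_somatic_tsv, result$snvs, "somatic_snvs.tsv")
  put(write_targets_bed, result$targets, "shm_targets.bed")
  put(write_json_file, result$manifest, "manifest.json")
  invisible(out_dir)
}
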