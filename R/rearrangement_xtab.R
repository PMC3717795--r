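#' Read rearrangement events from BEDPE or a sample/breakpoint TSV
#'
#' Two layouts are accepted: headered TSV with columns \code{sample_id},
#' \code{chrom_a}, \code{pos_a}, \code{chrom_b}, \code{pos_b} and optional
#' \code{event_class}; or headerless BEDPE whose 7th (name) column carries
#' the sample id, with an optional 8th class column. BEDPE breakpoints use
#' the start coordinate of each interval (already 0-based).
#'
#' @param path Path to the event file.
#' @return Data.frame with columns \code{sample_id}, \code{chrom_a},
#'   \code{pos_a}, \code{chrom_b}, \code{pos_b}, \code{event_class}.
#' @export
read_rearrangements <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("sample", first, ignore.case = TRUE)) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "chrom_a", "pos_a", "chrom_b", "pos_b")
    miss <- setdiff(need, names(tab))
    if (length(miss)) stop("event TSV missing column(s): ",
                           paste(miss, collapse = ", "))
    if (is.null(tab$event_class)) tab$event_class <- "other"
  } else {
    raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(raw) < 7) stop("BEDPE input needs >= 7 columns (name = sample id)")
    tab <- data.frame(sample_id = raw[[7]],
                      chrom_a = raw[[1]], pos_a = as.integer(raw[[2]]),
                      chrom_b = raw[[4]], pos_b = as.integer(raw[[5]]),
                      event_class = if (ncol(raw) >= 8) raw[[8]] else "other",
                      stringsAsFactors = FALSE)
  }
  tab[c("sample_id", "chrom_a", "pos_a", "chrom_b", "pos_b", "event_class")]
}

#' Map rearrangement breakpoints onto SHM-target vicinities
#'
#' An event touches a gene when either breakpoint falls inside the gene's
#' SHM-target window extended by \code{flank_bp} on both sides (half-open:
#' a breakpoint exactly at \code{end + flank_bp} is outside). Events are
#' deduplicated on (sample, breakpoints) first; an inter-chromosomal event
#' can touch several genes.
#'
#' @param events Data.frame from [read_rearrangements()].
#' @param targets Table from [derive_shm_targets()].
#' @param flank_bp Vicinity flank in bases; default 1e5, wide enough to
#'   capture promoter-region translocation breakpoints.
#' @return Named list: gene symbol -> character vector of sample ids with a
#'   breakpoint in the gene's vicinity.
#' @export
assign_events_to_genes <- function(events, targets, flank_bp = 1e5) {
  stopifnot(flank_bp >= 0)
  events <- events[!duplicated(events[c("sample_id", "chrom_a", "pos_a",
                                        "chrom_b", "pos_b")]), , drop = FALSE]
  bp <- rbind(
    data.frame(sample_id = events$sample_id, chrom = events$chrom_a,
               pos = events$pos_a, stringsAsFactors = FALSE),
    data.frame(sample_id = events$sample_id, chrom = events$chrom_b,
               pos = events$pos_b, stringsAsFactors = FALSE))
  out <- setNames(vector("list", nrow(targets)), targets$gene_symbol)
  for (i in seq_len(nrow(targets))) {
    tg <- targets[i, ]
    lo <- max(tg$start - flank_bp, 0)
    hi <- tg$end + flank_bp
    hit <- bp$chrom == tg$chrom & bp$pos >= lo & bp$pos < hi
    out[[tg$gene_symbol]] <- sort(unique(bp$sample_id[hit]))
  }
  out
}

#' Cross-tabulate mutation and rearrangement status per gene
#'
#' For every gene, counts cohort samples with both a somatic SNV in the
#' SHM-target and a rearrangement breakpoint in its vicinity, samples with
#' mutations only, and samples with neither. Samples with a rearrangement
#' but no mutation are reported in \code{n_rearr_only} so the four counts
#' always sum to the cohort size (conventional summaries omit that column).
#'
#' @param mutated_map Named list: gene -> mutated sample ids.
#' @param rearr_map Named list from [assign_events_to_genes()].
#' @param samples Character vector of all cohort sample ids.
#' @param genes Genes to report; defaults to the union of both maps.
#' @return Data.frame with columns \code{gene_symbol},
#'   \code{n_mut_and_rearr}, \code{n_mut_only}, \code{n_neither},
#'   \code{n_rearr_only}.
#' @export
mutation_rearrangement_table <- function(mutated_map, rearr_map, samples,
                                         genes = NULL) {
  if (is.null(genes)) genes <- sort(union(names(mutated_map), names(rearr_map)))
  rows <- lapply(genes, function(g) {
    mut <- intersect(mutated_map[[g]] %||% character(0), samples)
    rea <- intersect(rearr_map[[g]] %||% character(0), samples)
    both <- length(intersect(mut, rea))
    data.frame(gene_symbol = g,
               n_mut_and_rearr = both,
               n_mut_only = length(mut) - both,
               n_neither = length(samples) - length(union(mut, rea)),
               n_rearr_only = length(rea) - both,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write the mutation-by-rearrangement cross-tab as TSV
#'
#' Emits the three conventional columns (both, mutation-only, neither).
#'
#' @param xtab Table from [mutation_rearrangement_table()].
#' @param path Output path.
#' @export
write_rearrangement_table <- function(xtab, path) {
  write.table(xtab[c("gene_symbol", "n_mut_and_rearr", "n_mut_only",
                     "n_neither")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
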