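#' Read gene models from BED12, GTF, or a knownGene-style flat table
#'
#' Parses transcript records into a uniform table of transcript models with a
#' strand-aware transcription start site (TSS). Coordinates are 0-based
#' half-open internally: BED input is taken as-is, GTF is converted from
#' 1-based. The TSS is the start-of-transcription boundary: the leftmost
#' coordinate for \code{+} transcripts and the rightmost (half-open end)
#' coordinate for \code{-} transcripts.
#'
#' @param path Path to the annotation file.
#' @param format One of \code{"auto"}, \code{"bed12"} (any BED with >= 6
#'   columns), \code{"gtf"}, or \code{"flat_table"} (tab-separated with
#'   columns \code{name}, \code{chrom}, \code{strand}, \code{txStart},
#'   \code{txEnd}, \code{geneSymbol}; \code{txStart} 0-based).
#' @return A data.frame with columns \code{gene_symbol}, \code{transcript_id},
#'   \code{chrom}, \code{strand}, \code{tss}, \code{tx_start}, \code{tx_end}.
#' @export
read_gene_models <- function(path, format = c("auto", "bed12", "gtf", "flat_table")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext, bed = "bed12", gtf = "gtf", gff = "gtf", "flat_table")
  }
  models <- switch(format,
    bed12 = read_models_bed(path),
    gtf = read_models_gtf(path),
    flat_table = read_models_flat(path))
  validate_models(models)
}

read_models_bed <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("malformed BED record in ", path, ": ",
                                          conditionMessage(e)))
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*"))
    stop("missing strand in BED record(s) ",
         paste(head(which(strand == "*"), 5), collapse = ", "), " of ", path)
  name <- gr$name %||% stop("BED input must carry a name column (>= 6 fields)")
  data.frame(
    gene_symbol = name, transcript_id = name,
    chrom = as.character(GenomicRanges::seqnames(gr)), strand = strand,
    tx_start = GenomicRanges::start(gr) - 1L, tx_end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
}

read_models_gtf <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "GTF"),
                 error = function(e) stop("malformed GTF record in ", path, ": ",
                                          conditionMessage(e)))
  if (!is.null(gr$type) && any(gr$type == "transcript"))
    gr <- gr[gr$type == "transcript"]
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) stop("missing strand in GTF transcript record of ", path)
  gene <- gr$gene_name %||% NULL
  if (is.null(gene) || all(is.na(gene))) gene <- gr$gene_id
  if (is.null(gene)) stop("GTF input must carry gene_name or gene_id attributes")
  tx <- gr$transcript_id %||% gene
  data.frame(
    gene_symbol = as.character(gene), transcript_id = as.character(tx),
    chrom = as.character(GenomicRanges::seqnames(gr)), strand = strand,
    tx_start = GenomicRanges::start(gr) - 1L, tx_end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
}

read_models_flat <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "chrom", "strand", "txStart", "txEnd", "geneSymbol")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("flat table missing column(s): ", paste(miss, collapse = ", "))
  data.frame(
    gene_symbol = tab$geneSymbol, transcript_id = tab$name,
    chrom = tab$chrom, strand = tab$strand,
    tx_start = as.integer(tab$txStart), tx_end = as.integer(tab$txEnd),
    stringsAsFactors = FALSE)
}

validate_models <- function(models) {
  bad <- which(!models$strand %in% c("+", "-"))
  if (length(bad)) stop("invalid strand at record(s): ", paste(head(bad, 5), collapse = ", "))
  if (any(models$tx_end <= models$tx_start))
    stop("transcript with non-positive length found")
  models$tss <- ifelse(models$strand == "+", models$tx_start, models$tx_end)
  models[c("gene_symbol", "transcript_id", "chrom", "strand", "tss",
           "tx_start", "tx_end")]
}

#' Derive SHM-target windows downstream of transcription start sites
#'
#' An SHM-target is the window extending \code{window_bp} bases downstream of
#' a gene's TSS in the transcription direction: \code{[tss, tss + window_bp)}
#' on \code{+} and \code{[tss - window_bp, tss)} on \code{-}. In
#' \code{per_gene} mode one window is emitted per gene symbol, anchored at the
#' most upstream TSS in transcription direction (ties broken lexicographically
#' by transcript id); genes whose transcripts disagree on strand are skipped
#' with a warning. Windows truncated at contig edges are flagged.
#'
#' @param models Data.frame from [read_gene_models()].
#' @param window_bp Window length in bases (default 2000).
#' @param collapse \code{"per_gene"} or \code{"per_transcript"}.
#' @param seqlengths Optional named vector of contig lengths used to truncate
#'   windows at the right contig edge.
#' @return Data.frame with columns \code{gene_symbol}, \code{chrom},
#'   \code{strand}, \code{start}, \code{end}, \code{tss}, \code{window_bp},
#'   \code{truncated}.
#' @export
derive_shm_targets <- function(models, window_bp = 2000,
                               collapse = c("per_gene", "per_transcript"),
                               seqlengths = NULL) {
  collapse <- match.arg(collapse)
  stopifnot(window_bp > 0)
  if (collapse == "per_gene") {
    keep <- logical(0)
    parts <- split(seq_len(nrow(models)), models$gene_symbol)
    idx <- vapply(parts, function(ii) {
      sub <- models[ii, ]
      if (length(unique(sub$strand)) > 1L) {
        warning("gene ", sub$gene_symbol[1],
                " has transcripts on conflicting strands; skipped")
        return(NA_integer_)
      }
      # most upstream TSS in transcription direction
      best <- if (sub$strand[1] == "+") sub$tss == min(sub$tss) else sub$tss == max(sub$tss)
      cand <- sub[best, ]
      ii[best][order(cand$transcript_id)][1]
    }, integer(1))
    models <- models[idx[!is.na(idx)], , drop = FALSE]
  }
  start <- ifelse(models$strand == "+", models$tss, models$tss - window_bp)
  end <- ifelse(models$strand == "+", models$tss + window_bp, models$tss)
  truncated <- start < 0
  start <- pmax(start, 0)
  if (!is.null(seqlengths)) {
    len <- seqlengths[models$chrom]
    if (anyNA(len)) stop("contig absent from seqlengths: ",
                         paste(unique(models$chrom[is.na(len)]), collapse = ", "))
    truncated <- truncated | end > len
    end <- pmin(end, len)
  }
  out <- data.frame(
    gene_symbol = models$gene_symbol, chrom = models$chrom,
    strand = models$strand, start = as.integer(start), end = as.integer(end),
    tss = as.integer(models$tss), window_bp = as.integer(window_bp),
    truncated = truncated, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Mark positions covered by the WRCY/RGYW hypermutation hotspot motif
#'
#' A position is covered if it lies within any 4-mer matching WRCY
#' (W = A/T, R = A/G, Y = C/T) or its reverse complement RGYW on the given
#' strand. Matching is case-insensitive; ambiguity codes (N) never match.
#'
#' @param seq A character string or \code{Biostrings::DNAString}.
#' @return Logical vector of length \code{nchar(seq)}.
#' @export
scan_motif_mask <- function(seq) {
  s <- toupper(as.character(seq))
  n <- nchar(s)
  mask <- logical(n)
  if (n < 4L) return(mask)
  for (re in c("(?=[AT][AG]C[CT])", "(?=[AG]G[CT][AT])")) {
    hits <- gregexpr(re, s, perl = TRUE)[[1]]
    if (hits[1] != -1L) {
      for (k in 0:3) mask[hits + k] <- TRUE
    }
  }
  mask
}

#' Sequence-composition statistics for an SHM-target window
#'
#' Computes, over the window's reference bases, the C/G and A/T fractions
#' (ambiguity codes counted separately as \code{frac_other}) and the fraction
#' of positions covered by a WRCY/RGYW motif occurrence. These fractions are
#' the composition-correction success rates of the signature tests.
#'
#' @param target One row of the table from [derive_shm_targets()] (or a list
#'   with \code{chrom}, \code{start}, \code{end}).
#' @param genome A named \code{Biostrings::DNAStringSet}, or a FASTA path.
#' @return List with \code{n_bases}, \code{frac_cg}, \code{frac_at},
#'   \code{frac_other}, \code{frac_motif}, \code{motif_mask}, \code{offset}
#'   (window start, for mapping genomic positions onto the mask).
#' @export
region_sequence_stats <- function(target, genome) {
  genome <- load_genome(genome)
  chrom <- as.character(target$chrom)
  if (!chrom %in% names(genome)) stop("contig absent from genome: ", chrom)
  start <- as.integer(target$start); end <- as.integer(target$end)
  stopifnot(start >= 0, end <= length(genome[[chrom]]), end > start)
  seq <- as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end))
  region_stats_from_seq(seq, offset = start)
}

region_stats_from_seq <- function(seq, offset = 0L) {
  s <- toupper(seq)
  n <- nchar(s)
  bases <- strsplit(s, "", fixed = TRUE)[[1]]
  mask <- scan_motif_mask(s)
  n_cg <- sum(bases %in% c("C", "G"))
  n_at <- sum(bases %in% c("A", "T"))
  list(n_bases = n, frac_cg = n_cg / n, frac_at = n_at / n,
       frac_other = (n - n_cg - n_at) / n, frac_motif = mean(mask),
       motif_mask = mask, offset = as.integer(offset))
}

#' @keywords internal
load_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  stopifnot(methods::is(genome, "DNAStringSet"))
  genome
}

#' Write SHM-target windows as BED6
#'
#' @param targets Table from [derive_shm_targets()].
#' @param path Output path.
#' @export
write_targets_bed <- function(targets, path) {
  bed <- data.frame(targets$chrom, targets$start, targets$end,
                    targets$gene_symbol, 0L, targets$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
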