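#' Classify a single-nucleotide substitution
#'
#' Transitions are the purine-purine and pyrimidine-pyrimidine exchanges
#' (A<->G, C<->T); everything else is a transversion. The site class records
#' whether the reference base is C/G or A/T, the denominator of the
#' C:G-over-A:T bias statistic.
#'
#' @param ref,alt Character vectors of single bases in A/C/G/T.
#' @return Data.frame with columns \code{subst_class}
#'   (\code{"transition"}/\code{"transversion"}) and \code{site_class}
#'   (\code{"CG_site"}/\code{"AT_site"}).
#' @export
classify_substitution <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (length(ref) != length(alt)) stop("ref and alt must have equal length")
  if (!all(is_valid_base(ref)) || !all(is_valid_base(alt)))
    stop("ref and alt must be single bases in A/C/G/T")
  if (any(ref == alt)) stop("ref and alt must differ")
  data.frame(
    subst_class = ifelse(TRANSITION_PARTNER[ref] == alt, "transition", "transversion"),
    site_class = ifelse(ref %in% c("C", "G"), "CG_site", "AT_site"),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Default somatic-filter thresholds
#'
#' \code{min_quality} is the phred-scaled call-quality floor,
#' \code{min_alt_fraction} the minimum fraction of high-quality reads
#' (mapping quality > \code{mapq_min}, base quality > \code{baseq_min})
#' supporting the alternate allele. The mapq/baseq cutoffs document the
#' provenance of \code{alt_fraction_highqual}, which is computed upstream
#' (e.g. from a pileup) and supplied in the call table.
#'
#' @param min_quality,min_alt_fraction,mapq_min,baseq_min Numeric thresholds.
#' @return Named list of thresholds.
#' @export
somatic_thresholds <- function(min_quality = 20, min_alt_fraction = 0.20,
                               mapq_min = 25, baseq_min = 10) {
  list(min_quality = min_quality, min_alt_fraction = min_alt_fraction,
       mapq_min = mapq_min, baseq_min = baseq_min)
}

#' Read per-sample variant calls from a VCF
#'
#' Positions are converted to the package's 0-based convention; multi-allelic
#' records are decomposed into biallelic calls. The high-quality alternate
#' read fraction is taken from the \code{AFHQ} INFO tag when present
#' (\code{NA} otherwise, in which case the fraction filter does not apply).
#'
#' @param path Path to a VCF (optionally gzipped).
#' @param sample_id Sample label; defaults to the file name stem.
#' @return Data.frame of variant calls with columns \code{sample_id},
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{call_quality},
#'   \code{alt_fraction_highqual}.
#' @export
read_variant_calls <- function(path, sample_id = NULL) {
  if (is.null(sample_id))
    sample_id <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0)
    return(data.frame(sample_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      call_quality = numeric(), alt_fraction_highqual = numeric(),
                      stringsAsFactors = FALSE))
  afhq <- tryCatch(as.numeric(vcfR::extract.info(v, element = "AFHQ")),
                   warning = function(w) rep(NA_real_, nrow(fix)),
                   error = function(e) rep(NA_real_, nrow(fix)))
  if (length(afhq) != nrow(fix)) afhq <- rep(NA_real_, nrow(fix))
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  nalt <- lengths(alts)
  idx <- rep(seq_len(nrow(fix)), nalt)
  data.frame(
    sample_id = sample_id,
    chrom = fix[idx, "CHROM"],
    pos = as.integer(fix[idx, "POS"]) - 1L,
    ref = fix[idx, "REF"],
    alt = unlist(alts),
    call_quality = suppressWarnings(as.numeric(fix[idx, "QUAL"])),
    alt_fraction_highqual = afhq[idx],
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a variant site set used for filtering
#'
#' Accepts a VCF (positions converted to 0-based) or a 3-column
#' tab-separated file \code{chrom}, \code{pos} (0-based), \code{alt}.
#' Sites are keyed by (chrom, pos, alt).
#'
#' @param path Path to the site file.
#' @return Character vector of \code{chrom:pos:alt} keys.
#' @export
read_site_set <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    calls <- read_variant_calls(path, sample_id = "sites")
    return(unique(site_key(calls$chrom, calls$pos, calls$alt)))
  }
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos", "alt") %in% names(tab))) {
    tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    names(tab)[1:3] <- c("chrom", "pos", "alt")
  }
  unique(site_key(tab$chrom, as.integer(tab$pos), tab$alt))
}

site_key <- function(chrom, pos, alt) paste(chrom, pos, alt, sep = ":")

#' Filter tumor variant calls down to putative somatic SNVs
#'
#' Retains biallelic SNVs that are absent from the matched-normal and
#' population site sets, meet the call-quality floor, and are supported by a
#' sufficient fraction of high-quality reads. Retained calls are classified
#' by substitution and site class and sorted by (chrom, pos, sample_id).
#'
#' @param tumor Data.frame of calls as from [read_variant_calls()] (possibly
#'   several samples concatenated).
#' @param matched_normal,population Site-set key vectors from
#'   [read_site_set()] (or \code{NULL}).
#' @param thresholds List from [somatic_thresholds()].
#' @return Data.frame of somatic SNVs with added columns \code{subst_class}
#'   and \code{site_class}.
#' @export
filter_somatic <- function(tumor, matched_normal = NULL, population = NULL,
                           thresholds = somatic_thresholds()) {
  if (nrow(tumor) == 0) {
    tumor$subst_class <- character(0); tumor$site_class <- character(0)
    return(tumor)
  }
  ref <- toupper(tumor$ref); alt <- toupper(tumor$alt)
  keep <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% DNA_BASES & alt %in% DNA_BASES & ref != alt
  keep <- keep & !is.na(tumor$call_quality) &
    tumor$call_quality >= thresholds$min_quality
  af <- tumor$alt_fraction_highqual
  keep <- keep & (is.na(af) | af >= thresholds$min_alt_fraction)
  key <- site_key(tumor$chrom, tumor$pos, alt)
  if (!is.null(matched_normal)) keep <- keep & !key %in% matched_normal
  if (!is.null(population)) keep <- keep & !key %in% population
  out <- tumor[keep, , drop = FALSE]
  if (nrow(out)) {
    cls <- classify_substitution(out$ref, out$alt)
    out$subst_class <- cls$subst_class
    out$site_class <- cls$site_class
    out <- out[order(out$chrom, out$pos, out$sample_id), , drop = FALSE]
  } else {
    out$subst_class <- character(0); out$site_class <- character(0)
  }
  rownames(out) <- NULL
  out
}

#' Write somatic SNVs as TSV
#' @param snvs Data.frame from [filter_somatic()].
#' @param path Output path.
#' @export
write_somatic_tsv <- function(snvs, path) {
  write.table(snvs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write somatic SNVs as a minimal VCF
#'
#' Emits one record per call with INFO tags \code{SAMPLE}, \code{SUBST_CLASS}
#' and \code{SITE_CLASS}; positions are written 1-based.
#'
#' @param snvs Data.frame from [filter_somatic()].
#' @param path Output path.
#' @export
write_somatic_vcf <- function(snvs, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Sample identifier\">",
    "##INFO=<ID=SUBST_CLASS,Number=1,Type=String,Description=\"transition or transversion\">",
    "##INFO=<ID=SITE_CLASS,Number=1,Type=String,Description=\"CG_site or AT_site\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(snvs)) sprintf(
    "%s\t%d\t.\t%s\t%s\t%s\tPASS\tSAMPLE=%s;SUBST_CLASS=%s;SITE_CLASS=%s",
    snvs$chrom, snvs$pos + 1L, snvs$ref, snvs$alt,
    formatC(snvs$call_quality, format = "g"),
    snvs$sample_id, snvs$subst_class, snvs$site_class) else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}
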