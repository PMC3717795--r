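#' Configuration of a synthetic aSHM cohort
#'
#' Parameterizes a self-contained simulated cohort emulating the AID
#' mutational process: a background somatic process over the whole genome
#' plus, in designated aSHM genes, an elevated process confined to the
#' SHM-target window with exponentially decaying distance-to-TSS density,
#' increased relative rate at WRCY/RGYW motif-covered bases and at C:G
#' sites, a transition excess over the 1:3 random expectation, optional
#' coupling of mutation intensity to expression, and co-occurring
#' rearrangement breakpoints. Defaults are the "dlbcl-like" preset: a
#' 40-sample cohort with a background rate of 2e-6 mutations per base per
#' sample, a 50-fold aSHM rate elevation (the gap reported between
#' immunoglobulin and non-immunoglobulin SHM), 700-bp positional decay,
#' 3-fold motif elevation, transition probability 0.5 against the 1/3
#' random expectation, and 1.5-fold C:G-site elevation on human-like 42%
#' GC sequence.
#'
#' @param seed Integer seed governing every realization.
#' @param n_samples Cohort size.
#' @param n_genes Number of simulated genes.
#' @param frac_ashm_genes Fraction of genes designated true aSHM targets.
#' @param window_bp SHM-target window length (default 2000).
#' @param background_rate Background mutations per base per sample.
#' @param ashm_rate_multiplier Window rate elevation in aSHM genes (>= 1).
#' @param positional_decay_mean Exponential scale (bases) of the
#'   distance-to-TSS density; \code{Inf} gives uniform placement.
#' @param motif_multiplier Relative per-base rate at motif-covered bases.
#' @param transition_bias Probability an aSHM mutation is a transition
#'   (null 1/3).
#' @param cg_bias Relative per-base rate at C:G versus A:T sites.
#' @param expression_coupling Exponent linking a sample's relative RPKM to
#'   its mutation intensity in aSHM genes (0 = uncoupled).
#' @param rearrangement_rate Expected rearrangement events per sample.
#' @param rearr_ashm_preference Probability an event's first breakpoint is
#'   placed at an aSHM gene.
#' @param gc_content GC fraction of the generated reference sequence.
#' @param gene_slot_bp Per-gene genomic slot (default 15000, leaving room
#'   for a 12-kb downstream profile window).
#' @param genes_per_contig Genes placed per contig (default 50).
#' @param germline_rate Planted per-sample germline variants per base.
#' @param population_rate Planted shared population variant sites per base.
#' @param artifact_rate Low-quality artifact calls as a fraction of somatic
#'   calls.
#' @param expr_meanlog,expr_sdlog Log-normal baseline RPKM parameters.
#' @param expr_noise_sdlog Per-sample log-normal RPKM noise.
#' @return List of class \code{ashm_cohort_config}.
#' @export
cohort_config <- function(seed = 1L, n_samples = 40, n_genes = 500,
                          frac_ashm_genes = 0.1, window_bp = 2000,
                          background_rate = 2e-6, ashm_rate_multiplier = 50,
                          positional_decay_mean = 700, motif_multiplier = 3,
                          transition_bias = 0.5, cg_bias = 1.5,
                          expression_coupling = 1, rearrangement_rate = 0.5,
                          rearr_ashm_preference = 0.8, gc_content = 0.42,
                          gene_slot_bp = 15000, genes_per_contig = 50,
                          germline_rate = 5e-6, population_rate = 5e-6,
                          artifact_rate = 0.1, expr_meanlog = 3,
                          expr_sdlog = 1.5, expr_noise_sdlog = 0.4) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_samples >= 1, cfg$n_genes >= 1, cfg$window_bp > 0,
            cfg$frac_ashm_genes >= 0, cfg$frac_ashm_genes <= 1,
            cfg$background_rate >= 0, cfg$ashm_rate_multiplier >= 1,
            cfg$positional_decay_mean > 0, cfg$motif_multiplier >= 0,
            cfg$transition_bias > 0, cfg$transition_bias < 1,
            cfg$cg_bias >= 0, cfg$expression_coupling >= 0,
            cfg$rearrangement_rate >= 0, cfg$gc_content >= 0,
            cfg$gc_content <= 1, cfg$gene_slot_bp >= cfg$window_bp)
  structure(cfg, class = "ashm_cohort_config")
}

#' Generate a synthetic reference genome and gene models
#'
#' Places \code{n_genes} non-overlapping genes, alternating randomly between
#' strands, in fixed-size slots across contigs of i.i.d. sequence with the
#' configured GC content. Genes are positioned so that both the SHM-target
#' window and a 12-kb downstream profile window lie inside the contig.
#' Deterministic under the config seed.
#'
#' @param config From [cohort_config()].
#' @return List with \code{genome} (named \code{DNAStringSet}) and
#'   \code{models} (as from [read_gene_models()]).
#' @export
generate_reference <- function(config) {
  with_seed(config$seed, {
    gpc <- config$genes_per_contig
    n_contig <- ceiling(config$n_genes / gpc)
    contig_len <- gpc * config$gene_slot_bp
    probs <- c(A = (1 - config$gc_content) / 2, C = config$gc_content / 2,
               G = config$gc_content / 2, T = (1 - config$gc_content) / 2)
    seqs <- vapply(seq_len(n_contig), function(i)
      paste(sample(DNA_BASES, contig_len, replace = TRUE, prob = probs),
            collapse = ""), character(1))
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- sprintf("ctg%02d", seq_len(n_contig))
    strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
    slot <- (seq_len(config$n_genes) - 1L) %% gpc
    contig <- (seq_len(config$n_genes) - 1L) %/% gpc + 1L
    base <- slot * config$gene_slot_bp
    # '+' genes transcribe rightward from slot base + 1000; '-' genes
    # leftward from slot base + 14000, so 12 kb downstream room either way
    tx_start <- ifelse(strand == "+", base + 1000L, base + 4000L)
    tx_end <- ifelse(strand == "+", base + 11000L, base + 14000L)
    gene <- sprintf("G%04d", seq_len(config$n_genes))
    models <- data.frame(
      gene_symbol = gene, transcript_id = paste0(gene, ".1"),
      chrom = names(genome)[contig], strand = strand,
      tss = as.integer(ifelse(strand == "+", tx_start, tx_end)),
      tx_start = as.integer(tx_start), tx_end = as.integer(tx_end),
      stringsAsFactors = FALSE)
    list(genome = genome, models = models)
  })
}

#' Simulate per-sample expression (RPKM)
#'
#' Log-normal per-gene baseline abundance with independent per-sample
#' log-normal noise. Expression feeds back into the mutation process when
#' \code{expression_coupling > 0} (see [simulate_cohort()]).
#'
#' @param config From [cohort_config()].
#' @param gene_symbols Gene symbols (columns).
#' @param sample_ids Sample ids (rows).
#' @return Sample-by-gene RPKM matrix.
#' @export
simulate_expression <- function(config, gene_symbols, sample_ids) {
  with_seed(config$seed + 1L, {
    baseline <- rlnorm(length(gene_symbols), config$expr_meanlog,
                       config$expr_sdlog)
    noise <- matrix(rlnorm(length(sample_ids) * length(gene_symbols),
                           0, config$expr_noise_sdlog),
                    nrow = length(sample_ids))
    m <- sweep(noise, 2, baseline, `*`)
    dimnames(m) <- list(sample_ids, gene_symbols)
    m
  })
}

#' Simulate cohort mutation calls under the AID-signature process
#'
#' For every sample, background mutations fall as a Poisson process over the
#' whole genome with signature-free substitutions. In each designated aSHM
#' gene an additional Poisson number of mutations is placed inside the
#' SHM-target window by a categorical draw over window positions with
#' unnormalized weights \code{exp(-d/decay) * motif_multiplier^in_motif *
#' cg_bias^is_CG}; alternate alleles are transitions with probability
#' \code{transition_bias}, otherwise a uniform transversion. When an
#' expression matrix is supplied and coupling is positive, a sample's
#' intensity in an aSHM gene scales with its relative RPKM (normalized so
#' the cohort-mean intensity is unchanged). Germline variants (present in
#' the matched-normal and population site sets) and low-quality artifact
#' calls are planted so the somatic filter is exercised end-to-end.
#'
#' @param config From [cohort_config()].
#' @param reference From [generate_reference()].
#' @param expression Optional sample-by-gene RPKM matrix from
#'   [simulate_expression()].
#' @return List with \code{calls} (raw tumor variant calls),
#'   \code{normal_sites} and \code{population_sites} (data.frames with
#'   \code{chrom}, \code{pos}, \code{alt}), and \code{truth} (per-gene
#'   flags and realized somatic counts plus the realized parameters).
#' @export
simulate_cohort <- function(config, reference, expression = NULL) {
  genome <- reference$genome
  models <- reference$models
  targets <- derive_shm_targets(models, config$window_bp,
                                seqlengths = setNames(Biostrings::width(genome),
                                                      names(genome)))
  with_seed(config$seed + 2L, {
    sample_ids <- sprintf("S%02d", seq_len(config$n_samples))
    n_ashm <- round(config$frac_ashm_genes * config$n_genes)
    ashm_idx <- if (n_ashm > 0) sort(sample.int(config$n_genes, n_ashm)) else integer(0)
    is_ashm <- seq_len(config$n_genes) %in% ashm_idx
    contig_len <- setNames(Biostrings::width(genome), names(genome))
    total_bp <- sum(as.numeric(contig_len))
    chars <- lapply(seq_along(genome), function(i)
      strsplit(as.character(genome[[i]]), "", fixed = TRUE)[[1]])
    names(chars) <- names(genome)

    # per-ashm-gene window weights (position order = window left to right)
    wcache <- lapply(ashm_idx, function(g) {
      tg <- targets[g, ]
      st <- region_sequence_stats(tg, genome)
      seq_chars <- chars[[tg$chrom]][(tg$start + 1L):tg$end]
      d <- if (tg$strand == "+") seq_len(tg$end - tg$start) - 1L
           else tg$end - (tg$start:(tg$end - 1L))
      w <- exp(-d / config$positional_decay_mean) *
        config$motif_multiplier^st$motif_mask *
        config$cg_bias^(seq_chars %in% c("C", "G"))
      list(target = tg, weights = w, bases = seq_chars)
    })
    names(wcache) <- targets$gene_symbol[ashm_idx]

    coupling <- matrix(1, config$n_samples, length(ashm_idx),
                       dimnames = list(sample_ids, names(wcache)))
    if (!is.null(expression) && config$expression_coupling > 0 &&
        length(ashm_idx)) {
      for (j in seq_along(ashm_idx)) {
        g <- names(wcache)[j]
        x <- expression[sample_ids, g]
        f <- (x / mean(x))^config$expression_coupling
        coupling[, j] <- f / mean(f)
      }
    }

    calls <- list()
    realized <- matrix(0L, config$n_samples, config$n_genes,
                       dimnames = list(sample_ids, targets$gene_symbol))

    # shared population sites (germline polymorphisms)
    n_pop <- rpois(1, config$population_rate * total_bp)
    pop_sites <- random_sites(n_pop, contig_len, chars)
    normal_sites <- list()

    for (s in sample_ids) {
      # background somatic, signature-free
      n_bg <- rpois(1, config$background_rate * total_bp)
      bg <- random_sites(n_bg, contig_len, chars)
      bg$origin <- rep("background", nrow(bg))
      # aSHM process per designated gene
      ash <- list()
      for (j in seq_along(wcache)) {
        wc <- wcache[[j]]
        lam <- config$background_rate * config$ashm_rate_multiplier *
          config$window_bp * coupling[s, j]
        n_mut <- rpois(1, lam)
        if (n_mut == 0) next
        idx <- unique(sample.int(length(wc$weights), n_mut, replace = TRUE,
                                 prob = wc$weights))
        ref <- wc$bases[idx]
        alt <- draw_alt(ref, config$transition_bias)
        ash[[j]] <- data.frame(chrom = wc$target$chrom,
                               pos = wc$target$start + idx - 1L,
                               ref = ref, alt = alt, origin = "ashm",
                               stringsAsFactors = FALSE)
        realized[s, wc$target$gene_symbol] <-
          realized[s, wc$target$gene_symbol] + length(idx)
      }
      som <- rbind(bg, do.call(rbind, ash))
      som$call_quality <- round(runif(nrow(som), 30, 60), 1)
      som$alt_fraction_highqual <- round(runif(nrow(som), 0.25, 0.9), 3)
      # private germline: in tumor calls and in the matched-normal site set
      n_germ <- rpois(1, config$germline_rate * total_bp)
      germ <- random_sites(n_germ, contig_len, chars)
      # plus a 30% draw of the shared population sites
      shared <- pop_sites[runif(nrow(pop_sites)) < 0.3, , drop = FALSE]
      germ <- rbind(germ, shared)
      germ$origin <- rep("germline", nrow(germ))
      germ$call_quality <- round(runif(nrow(germ), 30, 60), 1)
      germ$alt_fraction_highqual <- round(runif(nrow(germ), 0.3, 0.7), 3)
      if (nrow(germ)) normal_sites[[s]] <- germ[c("chrom", "pos", "alt")]
      # low-quality artifacts that the filter must remove
      n_art <- rpois(1, config$artifact_rate * max(nrow(som), 1))
      art <- random_sites(n_art, contig_len, chars)
      art$origin <- rep("artifact", nrow(art))
      low_qual <- runif(nrow(art)) < 0.5
      art$call_quality <- ifelse(low_qual, round(runif(nrow(art), 2, 19), 1),
                                 round(runif(nrow(art), 30, 60), 1))
      art$alt_fraction_highqual <- ifelse(low_qual,
                                          round(runif(nrow(art), 0.25, 0.9), 3),
                                          round(runif(nrow(art), 0.01, 0.19), 3))
      all_calls <- rbind(som, germ, art)
      if (nrow(all_calls)) {
        all_calls$sample_id <- s
        calls[[s]] <- all_calls
      }
    }
    calls <- do.call(rbind, calls)
    if (is.null(calls))
      calls <- data.frame(sample_id = character(), chrom = character(),
                          pos = integer(), ref = character(),
                          alt = character(), call_quality = numeric(),
                          alt_fraction_highqual = numeric(),
                          origin = character(), stringsAsFactors = FALSE)
    rownames(calls) <- NULL
    normal <- unique(do.call(rbind, normal_sites))
    if (is.null(normal))
      normal <- data.frame(chrom = character(), pos = integer(),
                           alt = character(), stringsAsFactors = FALSE)
    truth <- list(
      genes = data.frame(gene_symbol = targets$gene_symbol,
                         is_ashm_target = is_ashm,
                         n_somatic_snvs = colSums(realized),
                         stringsAsFactors = FALSE),
      per_sample_counts = realized,
      params = unclass(config))
    list(calls = calls[c("sample_id", "chrom", "pos", "ref", "alt",
                         "call_quality", "alt_fraction_highqual", "origin")],
         normal_sites = normal,
         population_sites = pop_sites[c("chrom", "pos", "alt")],
         truth = truth, sample_ids = sample_ids, targets = targets)
  })
}

# uniform random variant sites over the genome; N bases never drawn because
# generated contigs contain none
random_sites <- function(n, contig_len, chars) {
  if (n == 0)
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), stringsAsFactors = FALSE))
  cum <- cumsum(as.numeric(contig_len))
  flat <- ceiling(runif(n) * sum(as.numeric(contig_len)))
  ci <- findInterval(flat - 1, c(0, cum))
  pos <- as.integer(flat - c(0, cum)[ci] - 1L)
  chrom <- names(contig_len)[ci]
  ref <- vapply(seq_len(n), function(i) chars[[chrom[i]]][pos[i] + 1L],
                character(1))
  alt <- draw_alt(ref, 1/3)
  out <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                    stringsAsFactors = FALSE)
  out[!duplicated(out[c("chrom", "pos")]), , drop = FALSE]
}

# transition with the given probability, else one of the two transversions
draw_alt <- function(ref, transition_bias) {
  n <- length(ref)
  if (n == 0) return(character(0))
  is_ti <- runif(n) < transition_bias
  ti <- TRANSITION_PARTNER[ref]
  tv <- vapply(seq_len(n), function(i) {
    others <- setdiff(DNA_BASES, c(ref[i], ti[i]))
    others[ceiling(runif(1) * 2)]
  }, character(1))
  unname(ifelse(is_ti, ti, tv))
}

#' Simulate rearrangement events
#'
#' Each sample receives a Poisson number of translocation-like events; with
#' probability \code{rearr_ashm_preference} the first breakpoint falls
#' inside a random aSHM gene's SHM-target window, otherwise uniformly on
#' the genome; the partner breakpoint is uniform on the genome.
#'
#' @param config From [cohort_config()].
#' @param reference From [generate_reference()].
#' @param truth Truth table from [simulate_cohort()].
#' @param sample_ids Cohort sample ids.
#' @return Data.frame in the layout of [read_rearrangements()].
#' @export
simulate_rearrangements <- function(config, reference, truth, sample_ids) {
  genome <- reference$genome
  contig_len <- setNames(Biostrings::width(genome), names(genome))
  targets <- derive_shm_targets(reference$models, config$window_bp,
                                seqlengths = contig_len)
  ashm <- targets[truth$genes$is_ashm_target, , drop = FALSE]
  with_seed(config$seed + 3L, {
    rows <- list()
    for (s in sample_ids) {
      n_ev <- rpois(1, config$rearrangement_rate)
      if (n_ev == 0) next
      for (e in seq_len(n_ev)) {
        if (nrow(ashm) && runif(1) < config$rearr_ashm_preference) {
          g <- ashm[ceiling(runif(1) * nrow(ashm)), ]
          chrom_a <- g$chrom
          pos_a <- g$start + as.integer(ceiling(runif(1) * (g$end - g$start))) - 1L
        } else {
          ci <- ceiling(runif(1) * length(contig_len))
          chrom_a <- names(contig_len)[ci]
          pos_a <- as.integer(ceiling(runif(1) * contig_len[ci])) - 1L
        }
        ci <- ceiling(runif(1) * length(contig_len))
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = s, chrom_a = chrom_a, pos_a = pos_a,
          chrom_b = names(contig_len)[ci],
          pos_b = as.integer(ceiling(runif(1) * contig_len[ci])) - 1L,
          event_class = "translocation", stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(sample_id = character(), chrom_a = character(),
                        pos_a = integer(), chrom_b = character(),
                        pos_b = integer(), event_class = character(),
                        stringsAsFactors = FALSE)
    out
  })
}

#' Simulate a complete synthetic aSHM cohort
#'
#' Orchestrates [generate_reference()], [simulate_expression()],
#' [simulate_cohort()] and [simulate_rearrangements()] into one
#' self-contained object. Fully deterministic under the config seed.
#'
#' @param config From [cohort_config()].
#' @return List with \code{config}, \code{genome}, \code{models},
#'   \code{targets}, \code{expression}, \code{calls}, \code{normal_sites},
#'   \code{population_sites}, \code{rearrangements}, \code{truth},
#'   \code{sample_ids}.
#' @export
simulate_ashm_cohort <- function(config = cohort_config()) {
  ref <- generate_reference(config)
  sample_ids <- sprintf("S%02d", seq_len(config$n_samples))
  expr <- simulate_expression(config, ref$models$gene_symbol, sample_ids)
  coh <- simulate_cohort(config, ref, expression = expr)
  rearr <- simulate_rearrangements(config, ref, coh$truth, coh$sample_ids)
  list(config = config, genome = ref$genome, models = ref$models,
       targets = coh$targets, expression = expr, calls = coh$calls,
       normal_sites = coh$normal_sites,
       population_sites = coh$population_sites,
       rearrangements = rearr, truth = coh$truth, sample_ids = coh$sample_ids)
}

#' Write a simulated cohort to disk in standard formats
#'
#' FASTA reference, BED12 gene models, one VCF per tumor sample (with the
#' \code{AFHQ} INFO tag), a matched-normal VCF, a population site TSV, an
#' expression TSV, a rearrangement TSV, and JSON truth/config records.
#'
#' @param sim From [simulate_ashm_cohort()].
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "reference.fa"))
  m <- sim$models
  bed12 <- data.frame(m$chrom, m$tx_start, m$tx_end, m$gene_symbol, 0L,
                      m$strand, m$tx_start, m$tx_end, "0,0,0", 1L,
                      m$tx_end - m$tx_start, 0L)
  write.table(bed12, file.path(dir, "genes.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  vcf_dir <- file.path(dir, "vcf")
  dir.create(vcf_dir, showWarnings = FALSE)
  for (s in sim$sample_ids) {
    calls <- sim$calls[sim$calls$sample_id == s, , drop = FALSE]
    write_calls_vcf(calls, file.path(vcf_dir, paste0(s, ".vcf")))
  }
  norm <- sim$normal_sites
  write_calls_vcf(data.frame(chrom = norm$chrom, pos = norm$pos,
                             ref = ".", alt = norm$alt, call_quality = 60,
                             alt_fraction_highqual = 0.5),
                  file.path(dir, "matched_normal.vcf"), ref_dot = TRUE)
  write.table(sim$population_sites, file.path(dir, "population_sites.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  expr_out <- data.frame(sample = rownames(sim$expression),
                         sim$expression, check.names = FALSE)
  write.table(expr_out, file.path(dir, "expression.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$rearrangements, file.path(dir, "rearrangements.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_json_file(sim$truth["genes"], file.path(dir, "truth.json"))
  write_json_file(unclass(sim$config), file.path(dir, "config.json"))
  invisible(dir)
}

write_calls_vcf <- function(calls, path, ref_dot = FALSE) {
  header <- c("##fileformat=VCFv4.2",
              "##INFO=<ID=AFHQ,Number=1,Type=Float,Description=\"High-quality alt read fraction\">",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  ord <- order(calls$chrom, calls$pos)
  calls <- calls[ord, , drop = FALSE]
  ref <- if (ref_dot) "N" else calls$ref
  body <- if (nrow(calls)) sprintf("%s\t%d\t.\t%s\t%s\t%.1f\t.\tAFHQ=%.3f",
                                   calls$chrom, calls$pos + 1L, ref, calls$alt,
                                   calls$call_quality,
                                   calls$alt_fraction_highqual) else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}
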