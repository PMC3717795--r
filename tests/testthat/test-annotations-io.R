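test_that("gene models parse identically from BED12, GTF and flat table", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t1000\t5000\tGENEA\t0\t+", "chr1\t1000\t5000\tGENEB\t0\t-"),
             bed)
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\tsrc\ttranscript\t1001\t5000\t.\t+\t.\t",
           'gene_name "GENEA"; transcript_id "GENEA";'),
    paste0("chr1\tsrc\ttranscript\t1001\t5000\t.\t-\t.\t",
           'gene_name "GENEB"; transcript_id "GENEB";')), gtf)
  flat <- tempfile(fileext = ".txt")
  writeLines(c("name\tchrom\tstrand\ttxStart\ttxEnd\tgeneSymbol",
               "GENEA\tchr1\t+\t1000\t5000\tGENEA",
               "GENEB\tchr1\t-\t1000\t5000\tGENEB"), flat)

  mb <- read_gene_models(bed, "bed12")
  mg <- read_gene_models(gtf, "gtf")
  mf <- read_gene_models(flat, "flat_table")

  # strand-plus TSS is the leftmost coordinate, strand-minus the rightmost
  expect_equal(mb$tss, c(1000, 5000))
  expect_equal(mb$strand, c("+", "-"))
  for (m in list(mg, mf)) {
    expect_equal(m[order(m$gene_symbol), c("gene_symbol", "chrom", "strand", "tss")],
                 mb[order(mb$gene_symbol), c("gene_symbol", "chrom", "strand", "tss")],
                 ignore_attr = TRUE)
  }
})

test_that("malformed annotation input is rejected with information", {
  flat <- tempfile(fileext = ".txt")
  writeLines(c("name\tchrom\ttxStart\ttxEnd\tgeneSymbol",
               "T1\tchr1\t0\t10\tG1"), flat)
  expect_error(read_gene_models(flat, "flat_table"), "strand")
  flat2 <- tempfile(fileext = ".txt")
  writeLines(c("name\tchrom\tstrand\ttxStart\ttxEnd\tgeneSymbol",
               "T1\tchr1\t?\t0\t10\tG1"), flat2)
  expect_error(read_gene_models(flat2, "flat_table"), "strand")
})

test_that("SHM-target windows extend downstream of the TSS per strand", {
  models <- data.frame(
    gene_symbol = c("A", "B"), transcript_id = c("A.1", "B.1"),
    chrom = "chr1", strand = c("+", "-"), tss = c(1000, 5000),
    tx_start = c(1000, 1000), tx_end = c(5000, 5000),
    stringsAsFactors = FALSE)
  tg <- derive_shm_targets(models, 2000)
  expect_equal(tg$start, c(1000, 3000))
  expect_equal(tg$end, c(3000, 5000))
  expect_false(any(tg$truncated))
  # window length conservation when nothing is truncated
  expect_equal(sum(tg$end - tg$start), 2 * 2000)
})

test_that("per-gene collapse picks the most upstream TSS and flags conflicts", {
  models <- data.frame(
    gene_symbol = c("A", "A", "B", "B"),
    transcript_id = c("A.2", "A.1", "B.1", "B.2"),
    chrom = "chr1", strand = c("+", "+", "-", "-"),
    tss = c(1200, 1000, 5000, 5600),
    tx_start = c(1200, 1000, 1000, 1600), tx_end = c(5000, 5000, 5000, 5600),
    stringsAsFactors = FALSE)
  tg <- derive_shm_targets(models, 2000, collapse = "per_gene")
  expect_equal(nrow(tg), 2)
  expect_equal(tg$start[tg$gene_symbol == "A"], 1000)  # min TSS on '+'
  expect_equal(tg$end[tg$gene_symbol == "B"], 5600)    # max TSS on '-'

  conflicted <- models
  conflicted$strand <- c("+", "-", "-", "-")
  expect_warning(tg2 <- derive_shm_targets(conflicted, 2000),
                 "conflicting strands")
  expect_false("A" %in% tg2$gene_symbol)
})

test_that("windows are truncated and flagged at contig edges", {
  models <- data.frame(
    gene_symbol = "E", transcript_id = "E.1", chrom = "c", strand = "-",
    tss = 500, tx_start = 100, tx_end = 500, stringsAsFactors = FALSE)
  tg <- derive_shm_targets(models, 2000, seqlengths = c(c = 1000))
  expect_equal(tg$start, 0)
  expect_equal(tg$end, 500)
  expect_true(tg$truncated)
})

test_that("motif mask matches the degenerate WRCY/RGYW templates", {
  expect_equal(scan_motif_mask("TACT"), rep(TRUE, 4))   # WRCY
  expect_equal(scan_motif_mask("AGTA"), rep(TRUE, 4))   # RGYW
  expect_equal(scan_motif_mask("GGGG"), rep(FALSE, 4))
  expect_equal(scan_motif_mask("NACT"), rep(FALSE, 4))  # N never matches
  expect_equal(scan_motif_mask("tact"), rep(TRUE, 4))   # case-insensitive
  expect_equal(scan_motif_mask(""), logical(0))
  expect_equal(scan_motif_mask("TAC"), rep(FALSE, 3))
})

test_that("motif mask equals naive 4-mer enumeration on random sequences", {
  set.seed(42)
  for (len in c(4, 17, 100, 1000)) {
    s <- random_dna(len)
    expect_equal(scan_motif_mask(s), naive_motif_mask(s), info = paste("len", len))
  }
})

test_that("motif coverage is strand-symmetric", {
  set.seed(11)
  for (i in 1:20) {
    s <- random_dna(200)
    expect_equal(mean(scan_motif_mask(s)),
                 mean(scan_motif_mask(reverse_complement(s))))
  }
})

test_that("region sequence stats count bases and motif coverage", {
  g <- make_genome(list(c = "TACTGGGG"))
  tg <- data.frame(gene_symbol = "X", chrom = "c", strand = "+",
                   start = 0L, end = 8L, stringsAsFactors = FALSE)
  st <- region_sequence_stats(tg, g)
  expect_equal(st$n_bases, 8)
  expect_equal(st$frac_motif, 0.5)          # only TACT covered
  expect_equal(st$frac_cg, 5 / 8)           # C,G,G,G,G
  expect_equal(st$frac_cg + st$frac_at + st$frac_other, 1)
  expect_length(st$motif_mask, 8)

  gn <- make_genome(list(c = "NNNNNNNN"))
  stn <- region_sequence_stats(tg, gn)
  expect_equal(stn$frac_cg, 0)
  expect_equal(stn$frac_at, 0)
  expect_equal(stn$frac_motif, 0)
  expect_equal(stn$frac_other, 1)

  expect_error(region_sequence_stats(
    data.frame(chrom = "absent", start = 0, end = 8), g), "contig")
})
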