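# small config for fast unit checks; the full preset runs in the
# acceptance suite
tiny_config <- function(...) {
  cohort_config(seed = 101, n_samples = 6, n_genes = 30,
                frac_ashm_genes = 0.2, ...)
}

test_that("reference generation is deterministic and respects GC content", {
  cfg <- tiny_config()
  r1 <- generate_reference(cfg)
  r2 <- generate_reference(cfg)
  expect_identical(as.character(r1$genome), as.character(r2$genome))
  expect_identical(r1$models, r2$models)

  expect_equal(nrow(r1$models), 30)
  expect_true(all(c("+", "-") %in% r1$models$strand))
  # realized GC within 3 sigma of the configured fraction
  n <- sum(Biostrings::width(r1$genome))
  gc <- sum(Biostrings::letterFrequency(r1$genome, c("C", "G"))) / n
  expect_lt(abs(gc - cfg$gc_content), 3 * sqrt(0.42 * 0.58 / n))
})

test_that("simulated cohort is deterministic and its files round-trip", {
  cfg <- tiny_config()
  s1 <- simulate_ashm_cohort(cfg)
  s2 <- simulate_ashm_cohort(cfg)
  expect_identical(s1$calls, s2$calls)
  expect_identical(s1$rearrangements, s2$rearrangements)
  expect_identical(s1$expression, s2$expression)

  dir <- tempfile()
  write_cohort(s1, dir)
  # FASTA, BED, VCF, expression, events re-read losslessly
  genome <- Biostrings::readDNAStringSet(file.path(dir, "reference.fa"))
  names(genome) <- sub("\\s.*$", "", names(genome))
  expect_equal(as.character(genome), as.character(s1$genome))
  models <- read_gene_models(file.path(dir, "genes.bed"), "bed12")
  expect_equal(models$tss, s1$models$tss)
  expect_equal(models$strand, s1$models$strand)
  vcfs <- list.files(file.path(dir, "vcf"), full.names = TRUE)
  expect_length(vcfs, cfg$n_samples)
  s01 <- read_variant_calls(vcfs[1])
  orig <- s1$calls[s1$calls$sample_id == s01$sample_id[1], ]
  orig <- orig[order(orig$chrom, orig$pos), ]
  expect_equal(s01$pos, orig$pos)
  expect_equal(s01$alt, orig$alt)
  expect_equal(s01$alt_fraction_highqual, orig$alt_fraction_highqual)
  expr <- read_expression(file.path(dir, "expression.tsv"))
  expect_equal(expr, s1$expression, tolerance = 1e-6)
  ev <- read_rearrangements(file.path(dir, "rearrangements.tsv"))
  expect_equal(nrow(ev), nrow(s1$rearrangements))
})

test_that("background mutation load matches its Poisson expectation", {
  cfg <- cohort_config(seed = 5, n_samples = 20, n_genes = 40,
                       frac_ashm_genes = 0, rearrangement_rate = 0)
  sim <- simulate_ashm_cohort(cfg)
  bg <- sum(sim$calls$origin == "background")
  lambda <- cfg$background_rate * 40 * cfg$gene_slot_bp * cfg$n_samples
  expect_lt(abs(bg - lambda), 4 * sqrt(lambda))
})

test_that("null transition bias yields the 1:2 transition:transversion ratio", {
  cfg <- cohort_config(seed = 6, n_samples = 30, n_genes = 60,
                       frac_ashm_genes = 1, transition_bias = 1/3,
                       motif_multiplier = 1, cg_bias = 1,
                       ashm_rate_multiplier = 50, rearrangement_rate = 0)
  sim <- simulate_ashm_cohort(cfg)
  som <- sim$calls[sim$calls$origin %in% c("background", "ashm"), ]
  cls <- classify_substitution(som$ref, som$alt)
  ti <- sum(cls$subst_class == "transition")
  n <- nrow(som)
  expect_gt(n, 300)
  expect_lt(abs(ti / n - 1/3), 3 * sqrt((1/3) * (2/3) / n))
})

test_that("planted mutations concentrate in true aSHM windows", {
  cfg <- tiny_config()
  sim <- simulate_ashm_cohort(cfg)
  truth <- sim$truth$genes
  expect_equal(sum(truth$is_ashm_target), round(0.2 * 30))
  ashm_calls <- sim$calls[sim$calls$origin == "ashm", ]
  tg <- sim$targets[sim$targets$gene_symbol %in%
                      truth$gene_symbol[truth$is_ashm_target], ]
  in_window <- mapply(function(ch, p) any(tg$chrom == ch & p >= tg$start &
                                            p < tg$end),
                      ashm_calls$chrom, ashm_calls$pos)
  expect_true(all(in_window))
})

test_that("rate-zero processes are silent and degenerate couplings are inert", {
  cfg <- cohort_config(seed = 9, n_samples = 4, n_genes = 10,
                       frac_ashm_genes = 0.5, rearrangement_rate = 0)
  sim <- simulate_ashm_cohort(cfg)
  expect_equal(nrow(sim$rearrangements), 0)

  # all-equal expression: coupling multiplies every intensity by 1
  ref <- generate_reference(cfg)
  flat_expr <- matrix(7, cfg$n_samples, cfg$n_genes,
                      dimnames = list(sprintf("S%02d", 1:4),
                                      ref$models$gene_symbol))
  c1 <- simulate_cohort(cfg, ref, expression = flat_expr)
  c2 <- simulate_cohort(cfg, ref, expression = NULL)
  expect_identical(c1$calls, c2$calls)
})

test_that("rearrangements prefer aSHM windows when preference is total", {
  cfg <- cohort_config(seed = 12, n_samples = 20, n_genes = 20,
                       frac_ashm_genes = 0.25, rearrangement_rate = 2,
                       rearr_ashm_preference = 1)
  sim <- simulate_ashm_cohort(cfg)
  expect_gt(nrow(sim$rearrangements), 0)
  ashm_tg <- sim$targets[sim$truth$genes$is_ashm_target, ]
  hit <- mapply(function(ch, p) any(ashm_tg$chrom == ch & p >= ashm_tg$start &
                                      p < ashm_tg$end),
                sim$rearrangements$chrom_a, sim$rearrangements$pos_a)
  expect_true(all(hit))
})
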