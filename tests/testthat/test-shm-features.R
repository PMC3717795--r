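make_profile <- function(total = 0, ti = 0, tv = 0, cg = 0, at = 0,
                         in_motif = 0, samples = character(0),
                         per_sample = integer(0)) {
  structure(list(gene_symbol = "G", n_snvs_total = total,
                 n_samples_mutated = length(unique(samples)),
                 n_transitions = ti, n_transversions = tv,
                 n_at_cg_sites = cg, n_at_at_sites = at,
                 n_in_motif = in_motif, per_sample_counts = per_sample,
                 mutated_samples = unique(samples), n_spilled = 0),
            class = "region_mutation_profile")
}

test_that("region mutation profiles count totals, samples, classes and motif hits", {
  g <- make_genome(list(c = paste0("TACT", strrep("G", 96))))
  tg <- data.frame(gene_symbol = "X", chrom = "c", strand = "+",
                   start = 0L, end = 100L, stringsAsFactors = FALSE)
  st <- region_sequence_stats(tg, g)
  snvs <- filter_somatic(rbind(
    make_calls("c", 1, "A", "G", "S1"),     # in motif
    make_calls("c", 50, "G", "A", "S1"),
    make_calls("c", 60, "G", "T", "S2"),
    make_calls("c", 400, "G", "T", "S2")))  # outside window -> spill
  prof <- count_region_mutations(tg, st, snvs)
  expect_equal(prof$n_snvs_total, 3)
  expect_equal(prof$n_samples_mutated, 2)
  expect_equal(prof$n_transitions, 2)
  expect_equal(prof$n_transversions, 1)
  expect_equal(prof$n_at_cg_sites, 2)
  expect_equal(prof$n_at_at_sites, 1)
  expect_equal(prof$n_in_motif, 1)
  expect_equal(prof$n_spilled, 1)
  expect_equal(sort(prof$mutated_samples), c("S1", "S2"))

  empty <- count_region_mutations(tg, st, snvs[0, ])
  expect_equal(empty$n_snvs_total, 0)
  expect_equal(empty$n_in_motif, 0)
})

test_that("mutation density averages per-sample counts over the window", {
  expect_equal(mutation_density(make_profile(total = 5), 2000, 2), 1.25e-3)
  expect_equal(mutation_density(make_profile(total = 0), 2000, 2), 0)
  expect_equal(mutation_density(make_profile(total = 4), 2000, 40), 5e-5)
  expect_error(mutation_density(make_profile(total = 1), 0, 2))
})

test_that("motif and C:G enrichments match composition expectation and exact tail", {
  st <- list(frac_motif = 0.2, frac_cg = 0.4, frac_at = 0.6)
  me <- motif_enrichment(make_profile(total = 10, in_motif = 6), st,
                         cap_at_half = FALSE)
  expect_equal(me$enrichment, 3.0)
  expect_equal(me$p, binom_tail_enum(6, 10, 0.2), tolerance = 1e-12)

  ce <- cg_at_enrichment(make_profile(total = 10, cg = 4, at = 6), st)
  expect_equal(ce$enrichment, 1.0)
  ce2 <- cg_at_enrichment(make_profile(total = 10, cg = 8, at = 2), st,
                          cap_at_half = FALSE)
  expect_equal(ce2$enrichment, 2.0)
  expect_equal(ce2$p, binom_tail_enum(8, 10, 0.4), tolerance = 1e-12)

  # no SNVs: enrichment missing, p = 1 (uncapped); capped reporting gives 0.5
  e0 <- motif_enrichment(make_profile(total = 0), st, cap_at_half = FALSE)
  expect_true(is.na(e0$enrichment))
  expect_equal(e0$p, 1)
  # zero observed successes: lower-tail observation, upper-tail p is 1
  elo <- motif_enrichment(make_profile(total = 4, in_motif = 0),
                          list(frac_motif = 0.5), cap_at_half = FALSE)
  expect_equal(elo$enrichment, 0)
  expect_equal(elo$p, 1)
})

test_that("Ti/Tv statistics test the transition count against the 1:3 null", {
  tt <- titv_stats(make_profile(total = 15, ti = 5, tv = 10), cap_at_half = FALSE)
  expect_equal(tt$ratio, 0.5)
  tt2 <- titv_stats(make_profile(total = 13, ti = 11, tv = 2), cap_at_half = FALSE)
  expect_equal(tt2$p, binom_tail_enum(11, 13, 1/3), tolerance = 1e-12)
  tt0 <- titv_stats(make_profile())
  expect_true(is.na(tt0$ratio))
  expect_equal(tt0$p, 1)
  expect_equal(titv_stats(make_profile(total = 3, ti = 3, tv = 0))$ratio, Inf)
})

test_that("burden test uses window/genome success rate; hypergeometric variant conditions on totals", {
  p <- region_burden_test(make_profile(total = 10), 100, 1e6, 2000)
  expect_equal(p, binom_tail_enum(10, 100, 0.002), tolerance = 1e-12)
  expect_equal(region_burden_test(make_profile(total = 0), 100, 1e6, 2000), 1)
  expect_equal(region_burden_test(make_profile(total = 7), 7, 2000, 2000), 1)
  ph <- region_burden_test(make_profile(total = 3), 10, 50, 20,
                           family = "hypergeometric")
  expect_equal(ph, hyper_tail_enum(3, 20, 10, 50), tolerance = 1e-12)
  expect_error(region_burden_test(make_profile(total = 10), 5, 1e6, 2000),
               "total")
})

test_that("exact upper tails match brute-force enumeration across a grid", {
  for (n in c(1, 5, 12, 25)) {
    for (rate in seq(0.1, 0.9, by = 0.2)) {
      for (k in c(0, 1, floor(n / 2), n)) {
        expect_equal(region_burden_test(make_profile(total = k), n,
                                        1 / rate * 1000, 1000),
                     binom_tail_enum(k, n, rate), tolerance = 1e-12)
      }
    }
  }
})

test_that("Benjamini-Hochberg adjustment follows the step-up rule", {
  expect_equal(benjamini_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(benjamini_adjust(0.2), 0.2)
  expect_equal(benjamini_adjust(rep(0.04, 5)), rep(0.04, 5))
  expect_equal(benjamini_adjust(numeric(0)), numeric(0))
  expect_error(benjamini_adjust(c(0.5, 0)))
})

test_that("SHM indicator is the geometric mean of the three signature p-values", {
  expect_equal(shm_indicator(0.5, 0.5, 0.5), 0.5)
  expect_equal(shm_indicator(1, 1, 1), 1)
  expect_equal(round(shm_indicator(0.0345, 0.1261, 0.5), 4), 0.1296)
  expect_equal(round(shm_indicator(0.0523, 0.5, 0.5), 4), 0.2356)
  # symmetric in its arguments
  set.seed(3)
  p <- runif(3)
  perms <- list(c(1,2,3), c(2,3,1), c(3,1,2), c(3,2,1))
  vals <- vapply(perms, function(i) shm_indicator(p[i[1]], p[i[2]], p[i[3]]),
                 numeric(1))
  expect_equal(max(vals) - min(vals), 0)
  expect_error(shm_indicator(0, 0.5, 0.5))
})

test_that("feature table keeps mutated targets sorted by SNV count then symbol", {
  set.seed(21)
  g <- make_genome(list(c = random_dna(9000)))
  tg <- data.frame(gene_symbol = c("AAA", "BBB", "CCC", "DDD"),
                   chrom = "c", strand = "+",
                   start = c(0L, 2000L, 4000L, 6000L),
                   end = c(2000L, 4000L, 6000L, 8000L),
                   tss = c(0L, 2000L, 4000L, 6000L),
                   stringsAsFactors = FALSE)
  snvs <- filter_somatic(rbind(
    make_calls("c", c(10, 20, 30), "C", "T", "S1"),      # AAA: 3
    make_calls("c", c(2010, 2020, 2030, 2040, 2050), "C", "T", "S2"),  # BBB: 5
    make_calls("c", c(4010, 4020, 4030), "C", "T", "S2")))  # CCC: 3
  ft <- build_feature_table(tg, g, snvs, n_samples = 2)
  expect_equal(ft$gene, c("BBB", "AAA", "CCC"))  # DDD absent (0 SNVs)
  expect_equal(ft$total_snvs, c(5, 3, 3))
  expect_true(all(ft$shm_indicator > 0 & ft$shm_indicator <= 1))
  expect_equal(ft$burden_q, benjamini_adjust(ft$burden_p))
  # expression columns are missing, not zero, without an expression matrix
  expect_true(all(is.na(ft$rpkm_fold_change)))
})

test_that("feature table TSV rounds to 4 decimals while JSON keeps full precision", {
  set.seed(22)
  g <- make_genome(list(c = random_dna(3000)))
  tg <- data.frame(gene_symbol = "AAA", chrom = "c", strand = "+",
                   start = 0L, end = 2000L, tss = 0L, stringsAsFactors = FALSE)
  snvs <- filter_somatic(make_calls("c", c(10, 20, 30), "C", "T", "S1"))
  ft <- build_feature_table(tg, g, snvs, n_samples = 2)
  tsv <- tempfile(fileext = ".tsv"); jsn <- tempfile(fileext = ".json")
  write_feature_table(ft, tsv, jsn)
  back_tsv <- read.delim(tsv)
  back_json <- jsonlite::fromJSON(jsn)
  expect_equal(back_tsv$shm_indicator, round(ft$shm_indicator, 4))
  expect_equal(back_json$shm_indicator, ft$shm_indicator, tolerance = 1e-12)
})
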