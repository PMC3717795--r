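# Shared, lazily-built simulation scans for the cohort-level checks. The
# "dlbcl-like" preset (40 samples, 500 genes, 10% true aSHM targets) is
# expensive enough that the coupling-on scan is built once and reused.

.preset_cache <- new.env(parent = emptyenv())

preset_scan <- function(key, config_fn) {
  if (!exists(key, envir = .preset_cache)) {
    cfg <- config_fn()
    sim <- simulate_ashm_cohort(cfg)
    normal_keys <- with(sim$normal_sites, paste(chrom, pos, alt, sep = ":"))
    pop_keys <- with(sim$population_sites, paste(chrom, pos, alt, sep = ":"))
    snvs <- filter_somatic(sim$calls, normal_keys, pop_keys)
    features <- build_feature_table(sim$targets, sim$genome, snvs,
                                    n_samples = cfg$n_samples,
                                    expr = sim$expression)
    assign(key, list(cfg = cfg, sim = sim, snvs = snvs, features = features),
           envir = .preset_cache)
  }
  get(key, envir = .preset_cache)
}

dlbcl_like_scan <- function() {
  preset_scan("dlbcl_like", function() cohort_config(seed = 424243))
}

uncoupled_scan <- function() {
  preset_scan("uncoupled", function()
    cohort_config(seed = 424244, expression_coupling = 0))
}
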