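#' @importFrom stats pbinom phyper p.adjust rpois rbinom runif rnorm rlnorm
#'   median ks.test fisher.test loess predict setNames complete.cases
#' @importFrom utils read.delim write.table packageVersion
NULL

DNA_BASES <- c("A", "C", "G", "T")

TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

#' @keywords internal
is_valid_base <- function(x) x %in% DNA_BASES

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Upper-tail exact binomial probability P(X >= k), X ~ Bin(n, rate).
# The workhorse behind every composition-corrected signature test.
#' @keywords internal
binom_upper_tail <- function(k, n, rate) {
  stopifnot(all(n >= 0), all(rate >= 0), all(rate <= 1))
  p <- ifelse(n == 0 | k <= 0, 1,
              pbinom(pmin(k, n) - 1, n, rate, lower.tail = FALSE))
  pmin(pmax(p, 0), 1)
}

# Upper-tail hypergeometric probability P(X >= k) of k marked draws when
# n draws are taken from N objects of which K are marked.
#' @keywords internal
hyper_upper_tail <- function(k, K, n, N) {
  stopifnot(N >= K, N >= n, k >= 0)
  if (k <= 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' @keywords internal
cap_half <- function(p, cap = TRUE) if (cap) pmin(p, 0.5) else p

# Seed handling: every stochastic entry point takes a seed and restores the
# caller's RNG state on exit.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' @keywords internal
round_df <- function(df, digits = 4) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) round(x, digits))
  df
}

#' @keywords internal
write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
}
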