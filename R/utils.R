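#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cor.test median qwilcox quantile rbinom runif sd
#'   shapiro.test wilcox.test dbinom setNames aggregate
#' @importFrom utils read.csv write.csv head modifyList
NULL

SCORES <- 1:5

# Derive a stage-specific RNG seed from a single top-level seed, so that
# every stochastic stage of a pipeline gets an independent but reproducible
# stream. Kept below 2^31 - 1.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

# Draw rows from a flat Dirichlet, strictly positive.
rdirichlet_rows <- function(n, k, alpha = 1) {
  g <- matrix(stats::rgamma(n * k, shape = alpha), nrow = n)
  g <- pmax(g, 1e-12)
  g / rowSums(g)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Sample one index per row of a row-stochastic probability matrix.
sample_categorical_rows <- function(prob) {
  cum <- t(apply(prob, 1L, cumsum))
  u <- runif(nrow(prob))
  1L + rowSums(cum < u)
}
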