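# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bbpls <- function(fmt, ..., class = "bbpls_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

# Independent sub-streams of the master seed: each stochastic stage draws
# from its own stream so that, e.g., changing n_permutations does not change
# the bootstrap draws. Offsets are fixed and documented in the run manifest.
# Result is kept below 2^31 - 1 (R integers are 32-bit).
substream_seed <- function(seed, stream = c("permutation", "bootstrap",
                                            "cv", "cv_null", "synthesis")) {
  stream <- match.arg(stream)
  offset <- c(permutation = 101L, bootstrap = 202L, cv = 303L,
              cv_null = 404L, synthesis = 505L)[[stream]]
  (as.integer(seed) + offset * 9973L) %% 2147483647L
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

assert_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_bbpls("'%s' must be a numeric matrix", name)
  invisible(x)
}

# Column skewness (biased moment estimator); used only for data screening.
col_skew <- function(X) {
  m <- colMeans(X)
  Xc <- sweep(X, 2L, m)
  s <- sqrt(colMeans(Xc^2))
  ifelse(s > 0, colMeans(Xc^3) / s^3, 0)
}
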