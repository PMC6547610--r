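# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Derive a stream-specific child seed from a base seed; stays below 2^31.
# Arithmetic in doubles (exact well past 2^31) to avoid integer overflow.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(stream) * 9973) %% 2147483629)
}

stopf <- function(fmt, ..., class = "picafuse_error") {
  abort(sprintf(fmt, ...), class = class)
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stopf("`%s` must be a positive finite scalar.", name,
          class = "picafuse_domain_error")
  }
  invisible(x)
}

# Sample standard deviation of each row of a matrix.
row_sds <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  sqrt(pmax(rowSums((x - m)^2) / (n - 1), 0))
}

col_sds <- function(x) {
  n <- nrow(x)
  xc <- sweep(x, 2L, colMeans(x))
  sqrt(pmax(colSums(xc^2) / (n - 1), 0))
}

# Skewness (biased moment estimator); used only for the sign convention.
row_skewness <- function(x) {
  m <- rowMeans(x)
  xc <- x - m
  s2 <- rowMeans(xc^2)
  rowMeans(xc^3) / (s2^1.5 + (s2 == 0))
}
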