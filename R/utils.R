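#' @useDynLib nigrastab, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd var median quantile plogis pt t.test
#' @importFrom utils write.csv read.csv head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals never disturb
#' the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-item seed derivation from a master seed; kept inside the
# 32-bit signed range required by set.seed().
derive_seed <- function(master, i) {
  as.integer((as.double(master) * 7919 + as.double(i) * 104729 + 17) %% 2147483647)
}

# Separable Gaussian smoothing of a 3D array; sigma given in mm, converted to
# voxels per axis via spacing. Edge rows are renormalized (truncated kernel).
smooth_gaussian3 <- function(a, sigma_mm, spacing) {
  d <- dim(a)
  for (axis in 1:3) {
    sig <- sigma_mm / spacing[axis]
    if (sig < 1e-8) next
    r <- max(1L, as.integer(ceiling(3 * sig)))
    k <- exp(-0.5 * ((-r:r) / sig)^2)
    n <- d[axis]
    M <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - r):(i + r)
      ok <- j >= 1 & j <= n
      M[i, j[ok]] <- k[ok] / sum(k[ok])
    }
    perm <- c(axis, setdiff(1:3, axis))
    b <- aperm(a, perm)
    b <- array(M %*% matrix(b, n), d[perm])
    a <- aperm(b, order(perm))
  }
  a
}

# Zero-mean, unit-variance spatially correlated noise field.
correlated_noise <- function(shape, correlation_length, spacing) {
  w <- array(rnorm(prod(shape)), shape)
  s <- smooth_gaussian3(w, correlation_length, spacing)
  sds <- stats::sd(as.vector(s))
  if (is.finite(sds) && sds > 0) s <- (s - mean(s)) / sds
  s
}
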