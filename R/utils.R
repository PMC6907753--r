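# Internal numerical helpers shared across modules.

#' @importFrom stats rnorm setNames aggregate
NULL

# Symmetrize a square matrix (guards against drift in Riccati recursions).
sym <- function(M) (M + t(M)) / 2

is_psd <- function(M, tol = 1e-10) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) return(FALSE)
  if (max(abs(M - t(M))) > tol * max(1, max(abs(M)))) return(FALSE)
  ev <- eigen(sym(M), symmetric = TRUE, only.values = TRUE)$values
  min(ev) > -tol * max(1, max(abs(ev)))
}

stopifnot_psd <- function(M, name) {
  if (!is_psd(M)) stop(sprintf("'%s' must be a symmetric positive semi-definite matrix", name))
  invisible(M)
}

# One multivariate normal draw per row request; PSD (possibly singular)
# covariance via eigendecomposition.
rmvn <- function(n, Sigma) {
  d <- nrow(Sigma)
  if (all(Sigma == 0)) return(matrix(0, n, d))
  e <- eigen(sym(Sigma), symmetric = TRUE)
  lam <- pmax(e$values, 0)
  Z <- matrix(rnorm(n * d), n, d)
  Z %*% (t(e$vectors) * sqrt(lam))
}

# Run `expr` under a temporarily-set RNG seed without disturbing the caller's
# RNG stream; seed = NULL leaves the stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
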