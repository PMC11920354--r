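# shared internal helpers

# round half away from zero, as in printed parameter tables
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

is_square_symmetric <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) &&
    max(abs(m - t(m))) <= tol * max(1, max(abs(m)))
}

# PSD check via eigenvalues; tolerance relative to largest magnitude
is_psd <- function(m, tol = 1e-8) {
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  min(ev) >= -tol * max(1, max(abs(ev)))
}

assert_psd <- function(m, name) {
  if (!is_square_symmetric(m)) {
    abort(sprintf("`%s` must be a square symmetric matrix.", name))
  }
  if (!is_psd(m)) {
    abort(sprintf("`%s` is not positive semi-definite.", name))
  }
  invisible(m)
}

# symmetric matrix square root (for PSD trait covariances; T is small)
psd_sqrt <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

# Cholesky of a relationship matrix, adding a small ridge when singular
chol_ridge <- function(G, ridge = 1e-6) {
  L <- tryCatch(chol(G), error = function(e) NULL)
  if (is.null(L)) {
    inform(sprintf(
      "relationship matrix not positive definite; adding ridge %g to diagonal",
      ridge
    ))
    L <- chol(G + diag(ridge * mean(diag(G)) + ridge, nrow(G)))
  }
  L
}

`%na%` <- function(x, y) ifelse(is.na(x), y, x)
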