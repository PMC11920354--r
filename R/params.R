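# heritability, repeatability, correlations -----------------------------------

check_variances <- function(sigma2_M, sigma2_A) {
  if (is.null(sigma2_M) == is.null(sigma2_A)) {
    abort("supply exactly one of `sigma2_M` (mother) or `sigma2_A` (additive).")
  }
  sigma2_M %||% (sigma2_A / 4)
}

#' Narrow-sense heritability from variance components
#'
#' `h2 = mean_diag_G * sigma2_A / (sigma2_M * mean_diag_G + sigma2_C +
#' sigma2_e)` with `sigma2_A = 4 sigma2_M` (the mother, i.e. half-sib
#' family, variance explains one quarter of the additive variance). The
#' mean diagonal of G enters because G is not scaled to unit average
#' inbreeding. The value is returned exactly as the formula gives it and is
#' *not* clamped to `[0, 1]`: it can exceed 1 when the permanent-environment
#' and residual variances are small.
#'
#' Variances may be given on the mother scale (`sigma2_M`) or the additive
#' scale (`sigma2_A`); supply exactly one.
#'
#' @param sigma2_M Mother (half-sib family) variance.
#' @param sigma2_C Permanent-environment variance.
#' @param sigma2_e Residual variance.
#' @param mean_diag_G Mean diagonal element of the relationship matrix used
#'   in the evaluation (see [grm_summary()]).
#' @param sigma2_A Additive variance (`4 sigma2_M`); alternative input.
#' @return The heritability (vectorised over component vectors).
#' @examples
#' heritability(sigma2_A = 60342.8, sigma2_C = 79075.3,
#'              sigma2_e = 482725.8, mean_diag_G = 1.26) # ~0.13
#' @export
heritability <- function(sigma2_M = NULL, sigma2_C, sigma2_e, mean_diag_G,
                         sigma2_A = NULL) {
  sigma2_M <- check_variances(sigma2_M, sigma2_A)
  if (any(c(sigma2_M, sigma2_C, sigma2_e) < 0)) {
    abort("variance components must be non-negative.")
  }
  den <- sigma2_M * mean_diag_G + sigma2_C + sigma2_e
  if (any(den <= 0)) abort("zero denominator: all variance components are 0.")
  mean_diag_G * 4 * sigma2_M / den
}

#' Repeatability from variance components
#'
#' `c2 = (mean_diag_G * sigma2_A + sigma2_C) / (sigma2_M * mean_diag_G +
#' sigma2_C + sigma2_e)`: the proportion of phenotypic variance explained
#' by additive plus permanent-environment effects. Shares its denominator
#' with [heritability()], so `c2 - h2 = sigma2_C / denominator >= 0`.
#'
#' @inheritParams heritability
#' @return The repeatability (vectorised).
#' @export
repeatability <- function(sigma2_M = NULL, sigma2_C, sigma2_e, mean_diag_G,
                          sigma2_A = NULL) {
  sigma2_M <- check_variances(sigma2_M, sigma2_A)
  if (any(c(sigma2_M, sigma2_C, sigma2_e) < 0)) {
    abort("variance components must be non-negative.")
  }
  den <- sigma2_M * mean_diag_G + sigma2_C + sigma2_e
  if (any(den <= 0)) abort("zero denominator: all variance components are 0.")
  (mean_diag_G * 4 * sigma2_M + sigma2_C) / den
}

#' Genetic correlation matrix
#'
#' Correlations of the additive covariance matrix `V_A = 4 V_M`; the factor
#' 4 cancels, so this equals the correlation matrix of the mother-level
#' covariances.
#'
#' @param V_M Mother-level trait covariance matrix (PSD, positive
#'   diagonal).
#' @return The genetic correlation matrix.
#' @export
genetic_correlations <- function(V_M) {
  V_M <- as.matrix(V_M)
  zero <- diag(V_M) <= 0
  if (any(zero)) {
    abort(sprintf("zero genetic variance for trait(s): %s",
                  paste(which(zero), collapse = ", ")))
  }
  stats::cov2cor(4 * V_M)
}

#' Phenotypic correlation matrix
#'
#' Correlations of `V_P = V_M + V_C + V_E`.
#'
#' @param V_M,V_C,V_E Trait covariance matrices (conformable).
#' @return The phenotypic correlation matrix.
#' @export
phenotypic_correlations <- function(V_M, V_C, V_E) {
  V_P <- as.matrix(V_M) + as.matrix(V_C) + as.matrix(V_E)
  zero <- diag(V_P) <= 0
  if (any(zero)) {
    abort(sprintf("zero phenotypic variance for trait(s): %s",
                  paste(which(zero), collapse = ", ")))
  }
  stats::cov2cor(V_P)
}

#' Genetic parameters from variance components
#'
#' Derives per-trait heritability and repeatability and the between-trait
#' genetic and phenotypic correlation matrices from a set of variance
#' components and the mean diagonal of the relationship matrix used in the
#' evaluation.
#'
#' @param vc A [variance_components()] object (or a fitted
#'   [em_reml()] result).
#' @param mean_diag_G Mean diagonal of G; take it from [grm_summary()].
#' @return An object of class `genetic_params`: `$params` (tibble with
#'   columns `trait`, `sigma2_M`, `sigma2_A`, `sigma2_C`, `sigma2_e`, `h2`,
#'   `c2`, and `se` columns that are `NA` -- standard errors are not
#'   computed), `$r_A` and `$r_P` correlation matrices, and
#'   `$mean_diag_G`.
#' @export
genetic_params <- function(vc, mean_diag_G) {
  if (inherits(vc, "reml_fit")) vc <- vc$vc
  stopifnot(inherits(vc, "variance_components"))
  sm <- diag(vc$V_M); sc <- diag(vc$V_C); se <- diag(vc$V_E)
  params <- tibble::tibble(
    trait = vc$traits,
    sigma2_M = sm,
    sigma2_A = 4 * sm,
    sigma2_C = sc,
    sigma2_e = se,
    h2 = heritability(sm, sc, se, mean_diag_G),
    c2 = repeatability(sm, sc, se, mean_diag_G),
    h2_se = NA_real_,
    c2_se = NA_real_
  )
  structure(
    list(params = params,
         r_A = genetic_correlations(vc$V_M),
         r_P = phenotypic_correlations(vc$V_M, vc$V_C, vc$V_E),
         mean_diag_G = mean_diag_G),
    class = "genetic_params"
  )
}

#' Combined parameter table
#'
#' A trait x trait matrix with heritabilities on the diagonal, genetic
#' correlations in the lower triangle, and phenotypic correlations in the
#' upper triangle, rounded half-up to two decimals for display.
#'
#' @param gp A [genetic_params()] object.
#' @param digits Decimals for display rounding.
#' @return A numeric matrix.
#' @export
param_table <- function(gp, digits = 2) {
  stopifnot(inherits(gp, "genetic_params"))
  m <- gp$r_P
  m[lower.tri(m)] <- gp$r_A[lower.tri(m)]
  diag(m) <- gp$params$h2
  round_half_up(m, digits)
}

#' @export
print.genetic_params <- function(x, ...) {
  cat(sprintf("<genetic_params> mean diag(G) = %.4g\n", x$mean_diag_G))
  print(x$params)
  cat("h2 on diagonal, genetic correlations below, phenotypic above:\n")
  print(param_table(x))
  invisible(x)
}
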