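# Beta-Binomial overdispersion -------------------------------------------------

#' Beta-Binomial log-likelihood of reference read counts
#'
#' Log-likelihood of observed reference read counts under the hierarchy
#' `R_A | p ~ Binomial(R_T, p)`, `p ~ Beta(mu, tau)` with the
#' location/dispersion parameterisation `alpha = mu(1-tau)/tau`,
#' `beta = (1-mu)(1-tau)/tau`. Cells with zero total reads carry no
#' information and are excluded. As `tau -> 0` the likelihood approaches
#' the Binomial likelihood continuously; `tau = 0` evaluates it exactly.
#'
#' @param tau Overdispersion parameter in `[0, 1)`.
#' @param ra Integer vector of reference read counts.
#' @param rt Integer vector of total read counts (`ra <= rt`).
#' @param mu Location parameter (the marker's mean allele frequency), in
#'   `(0, 1)`.
#' @return The summed log-likelihood (a scalar).
#' @examples
#' betabinomial_loglik(0.3, ra = c(3, 5, 0), rt = c(10, 8, 4), mu = 0.5)
#' @export
betabinomial_loglik <- function(tau, ra, rt, mu) {
  if (length(mu) != 1 || mu <= 0 || mu >= 1) {
    abort("`mu` must be a single value in (0, 1).")
  }
  if (length(tau) != 1 || tau < 0 || tau >= 1) {
    abort("`tau` must be a single value in [0, 1).")
  }
  if (any(ra > rt)) abort("`ra` must not exceed `rt`.")
  keep <- rt > 0
  ra <- ra[keep]
  rt <- rt[keep]
  if (!length(ra)) return(0)
  if (tau < 1e-12) {
    return(sum(dbinom(ra, rt, mu, log = TRUE)))
  }
  a <- mu * (1 - tau) / tau
  b <- (1 - mu) * (1 - tau) / tau
  sum(lchoose(rt, ra) + lbeta(ra + a, rt - ra + b) - lbeta(a, b))
}

#' Maximum-likelihood estimate of the overdispersion parameter
#'
#' Maximises [betabinomial_loglik()] over tau by bounded L-BFGS-B with a
#' moment-based start, falling back to a dense grid search when the
#' optimiser fails to converge (the estimate is then still returned, with
#' `converged = FALSE`). The location parameter is held fixed at the
#' marker's mean allele frequency.
#'
#' @inheritParams betabinomial_loglik
#' @param bounds Lower/upper bounds for tau.
#' @return A list: `tau` (the estimate), `mu`, `loglik` (maximised value),
#'   `converged`, `n_obs` (cells with reads).
#' @export
estimate_tau <- function(ra, rt, mu, bounds = c(1e-6, 1 - 1e-6)) {
  keep <- rt > 0
  n_obs <- sum(keep)
  if (n_obs < 2) {
    return(list(tau = NA_real_, mu = mu, loglik = NA_real_,
                converged = FALSE, n_obs = n_obs))
  }
  f <- ra[keep] / rt[keep]
  rbar <- mean(rt[keep])
  # moment start: Var[f] = mu(1-mu)[1+(R_T-1)tau]/R_T
  v <- mean((f - mu)^2)
  tau0 <- (v * rbar / (mu * (1 - mu)) - 1) / max(rbar - 1, 1)
  tau0 <- min(max(tau0, bounds[1]), bounds[2])
  nll <- function(t) -betabinomial_loglik(t, ra, rt, mu)
  fit <- tryCatch(
    optim(tau0, nll, method = "L-BFGS-B",
          lower = bounds[1], upper = bounds[2]),
    error = function(e) NULL
  )
  if (is.null(fit) || fit$convergence != 0) {
    grid <- seq(bounds[1], bounds[2], length.out = 400)
    ll <- vapply(grid, function(t) -nll(t), numeric(1))
    return(list(tau = grid[which.max(ll)], mu = mu, loglik = max(ll),
                converged = FALSE, n_obs = n_obs))
  }
  list(tau = min(max(fit$par, bounds[1]), bounds[2]), mu = mu,
       loglik = -fit$value, converged = TRUE, n_obs = n_obs)
}

#' Per-marker overdispersion estimates for a genotype matrix
#'
#' Runs [estimate_tau()] marker by marker on the supporting read counts of
#' a `cont_geno` object, fixing each marker's location parameter at its
#' mean observed allele frequency.
#'
#' @param cg A `cont_geno` object (merged; imputation does not matter since
#'   cells with zero reads are excluded from the likelihood).
#' @param bounds Lower/upper bounds for tau.
#' @return A tibble with one row per marker: `marker`, `mu`, `tau`,
#'   `omega` (heterogeneity factor at the marker's mean depth), `loglik`,
#'   `converged`, `mean_depth`.
#' @export
estimate_tau_markers <- function(cg, bounds = c(1e-6, 1 - 1e-6)) {
  stopifnot(inherits(cg, "cont_geno"))
  st <- marker_stats(cg)
  fits <- purrr::map(seq_len(ncol(cg$ra)), function(j) {
    mu <- st$fbar[j]
    if (is.na(mu) || mu <= 0 || mu >= 1) {
      return(list(tau = NA_real_, loglik = NA_real_, converged = FALSE))
    }
    estimate_tau(cg$ra[, j], cg$rt[, j], mu, bounds)
  })
  tau <- purrr::map_dbl(fits, "tau")
  tibble::tibble(
    marker = st$marker,
    mu = st$fbar,
    tau = tau,
    omega = ifelse(is.na(tau), NA_real_,
                   heterogeneity_factor(tau %na% 0, pmax(st$mean_depth, 1))),
    loglik = purrr::map_dbl(fits, "loglik"),
    converged = purrr::map_lgl(fits, "converged"),
    mean_depth = st$mean_depth
  )
}

#' Heterogeneity factor
#'
#' The per-marker multiplier `omega = [1 + (depth - 1) tau] / depth`
#' converting `fbar (1 - fbar)` into the variance of a continuous genotype
#' under Beta-Binomial read sampling. With `tau = 0` it is `1/depth`; as
#' depth grows it tends to `tau`.
#'
#' @param tau Overdispersion in `[0, 1)` (vectorised).
#' @param mean_depth Mean total read depth, `>= 1` (vectorised).
#' @return Numeric vector of heterogeneity factors in `(0, 1]`.
#' @examples
#' heterogeneity_factor(0, 10)    # 0.1
#' heterogeneity_factor(0.3, 100) # 0.307
#' @export
heterogeneity_factor <- function(tau, mean_depth) {
  if (any(mean_depth < 1)) abort("`mean_depth` must be at least 1.")
  if (any(tau < 0 | tau >= 1)) abort("`tau` must lie in [0, 1).")
  (1 + (mean_depth - 1) * tau) / mean_depth
}

# scaling factors --------------------------------------------------------------

#' Naive (Binomial/ploidy) scaling factor
#'
#' `h = (1/k) * sum_j fbar_j (1 - fbar_j)`.
#'
#' @param fbar Vector of per-marker mean allele frequencies in `(0, 1)`.
#' @param k Ploidy (`>= 2`).
#' @return The scaling factor `h > 0`.
#' @export
scaling_naive <- function(fbar, k) {
  if (k < 2) abort("ploidy `k` must be at least 2.")
  h <- sum(fbar * (1 - fbar)) / k
  if (h <= 0) abort("scaling factor is zero: all mean frequencies are 0 or 1.")
  h
}

#' Beta-Binomial scaling factor
#'
#' `h = sum_j fbar_j (1 - fbar_j) * omega_j` with the heterogeneity factor
#' `omega_j = [1 + (depth_j - 1) tau_j] / depth_j`. No ploidy term appears:
#' the read-sampling variance it models replaces the Binomial/ploidy
#' variance of the naive scaling.
#'
#' @param fbar Vector of per-marker mean allele frequencies.
#' @param marker_mean_depth Vector of per-marker mean total read depths.
#' @param tau Vector of per-marker overdispersion estimates.
#' @return The scaling factor `h > 0`.
#' @export
scaling_betabinomial <- function(fbar, marker_mean_depth, tau) {
  if (length(fbar) != length(marker_mean_depth) ||
      length(fbar) != length(tau)) {
    abort("`fbar`, `marker_mean_depth` and `tau` must have equal length.")
  }
  h <- sum(fbar * (1 - fbar) * heterogeneity_factor(tau, marker_mean_depth))
  if (h <= 0) abort("scaling factor is zero: all mean frequencies are 0 or 1.")
  h
}

# G construction ---------------------------------------------------------------

new_grm <- function(G, h, method, ploidy = NA_real_, indiv_mean_depth = NULL,
                    marker_mean_depth = NULL, tau = NULL, w = NULL) {
  structure(
    list(G = G, h = h, method = method, ploidy = ploidy,
         indiv_mean_depth = indiv_mean_depth,
         marker_mean_depth = marker_mean_depth, tau = tau, w = w),
    class = "grm"
  )
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm> %d individuals, method = %s, h = %.6g\n",
              nrow(x$G), x$method, x$h))
  s <- grm_summary(x)
  cat(sprintf("mean diag %.4f, mean off-diag %.4f\n",
              s$mean_diag, s$mean_offdiag))
  invisible(x)
}

#' Build a genomic relationship matrix from a complete genotype matrix
#'
#' `G = (F - 1 fbar')(F - 1 fbar')' / h`: the cross-product of
#' column-centred continuous genotypes divided by a scaling factor. With
#' `fbar` equal to the column means of `F` (the default) every row of `G`
#' sums to zero.
#'
#' @param f Complete (post-imputation) individuals x markers matrix of
#'   continuous genotypes.
#' @param h Scaling factor from [scaling_naive()] or
#'   [scaling_betabinomial()].
#' @param fbar Centering vector; defaults to `colMeans(f)`.
#' @param method Tag recorded on the result (`"naive"`, `"debiased"`,
#'   `"betabinomial"`, or free-form).
#' @param ... Extra fields stored on the `grm` object (e.g. `ploidy`,
#'   depth vectors, the tau table).
#' @return A `grm` object.
#' @export
build_grm <- function(f, h, fbar = colMeans(f), method = "custom", ...) {
  if (any(is.na(f))) abort("`f` must be complete; run impute_missing() first.")
  if (h <= 0) abort("scaling factor `h` must be positive.")
  fc <- sweep(f, 2, fbar)
  G <- tcrossprod(fc) / h
  dimnames(G) <- list(rownames(f), rownames(f))
  new_grm(G, h = h, method = method, ...)
}

#' Diagonal de-biasing of a naively scaled G
#'
#' Multiplies each diagonal element by `(1 - w_i)` with
#' `w_i = (k - 1) / (mean_depth_i + k - 1)`, the Binomial-sampling
#' adjustment for individual `i`'s mean total read depth. Off-diagonal
#' elements are untouched. Note this intentionally breaks the
#' rows-sum-to-zero property of the centred G.
#'
#' @param grm_naive A `grm` built with the naive scaling.
#' @param indiv_mean_depth Per-individual mean total read depth (averaged
#'   across markers).
#' @param k Ploidy.
#' @return A `grm` with method `"debiased"` and the adjustment factors
#'   stored in `$w`.
#' @export
debias_grm <- function(grm_naive, indiv_mean_depth, k) {
  stopifnot(inherits(grm_naive, "grm"))
  n <- nrow(grm_naive$G)
  if (length(indiv_mean_depth) != n) {
    abort("`indiv_mean_depth` must have one value per individual.")
  }
  w <- (k - 1) / (indiv_mean_depth + k - 1)
  G <- grm_naive$G
  diag(G) <- diag(G) * (1 - w)
  new_grm(G, h = grm_naive$h, method = "debiased", ploidy = k,
          indiv_mean_depth = indiv_mean_depth,
          marker_mean_depth = grm_naive$marker_mean_depth,
          w = setNames(w, rownames(G)))
}

#' Summary statistics of a relationship matrix
#'
#' @param grm A `grm` object (or plain matrix).
#' @return A one-row tibble: `method`, `h`, `mean_diag`, `mean_offdiag`,
#'   and `mean_inbreeding` (mean diagonal minus 1, the implied genomic
#'   inbreeding coefficient).
#' @export
grm_summary <- function(grm) {
  G <- if (inherits(grm, "grm")) grm$G else as.matrix(grm)
  n <- nrow(G)
  d <- mean(diag(G))
  off <- if (n > 1) (sum(G) - sum(diag(G))) / (n * (n - 1)) else NA_real_
  tibble::tibble(
    method = if (inherits(grm, "grm")) grm$method else "matrix",
    h = if (inherits(grm, "grm")) grm$h else NA_real_,
    mean_diag = d,
    mean_offdiag = off,
    mean_inbreeding = d - 1
  )
}

#' Genomic relationship matrix from continuous genotypes
#'
#' High-level constructor running the whole G stage on a `cont_geno`
#' object: computes per-marker statistics, estimates per-marker
#' overdispersion when needed, forms the requested scaling factor, imputes
#' missing genotypes with the marker mean if not already done, and builds
#' (and for `"debiased"`, corrects) the relationship matrix.
#'
#' @param cg A merged `cont_geno` object (imputed or not).
#' @param method `"betabinomial"` (default), `"naive"`, or `"debiased"`.
#' @param ploidy Ploidy `k` used by the naive and debiased scalings.
#' @param tau_bounds Bounds passed to [estimate_tau()].
#' @return A `grm` object; for the Beta-Binomial method its `$tau` field
#'   holds the per-marker tau/omega table.
#' @examples
#' cfg <- sim_config(n_mothers = 30, n_markers = 60, n_families = 3, seed = 2)
#' genos <- simulate_population(cfg)
#' cg <- continuous_genotypes(simulate_reads(genos, cfg))
#' g <- genomic_relationship(cg, method = "naive", ploidy = 6)
#' grm_summary(g)
#' @export
genomic_relationship <- function(cg,
                                 method = c("betabinomial", "naive",
                                            "debiased"),
                                 ploidy = 6,
                                 tau_bounds = c(1e-6, 1 - 1e-6)) {
  stopifnot(inherits(cg, "cont_geno"))
  method <- match.arg(method)
  st <- marker_stats(cg)
  bad <- is.na(st$fbar) | st$fbar <= 0 | st$fbar >= 1
  if (any(bad)) {
    abort(sprintf(
      "%d marker(s) have mean frequency 0 or 1; filter on MAF first.",
      sum(bad)
    ))
  }
  cgc <- if (cg$imputed) cg else impute_missing(cg)
  indiv_depth <- rowMeans(cg$rt)
  tau_tbl <- NULL
  if (method == "betabinomial") {
    tau_tbl <- estimate_tau_markers(cg, bounds = tau_bounds)
    h <- scaling_betabinomial(st$fbar, pmax(st$mean_depth, 1),
                              tau_tbl$tau %na% 0)
  } else {
    h <- scaling_naive(st$fbar, ploidy)
  }
  g <- build_grm(cgc$f, h = h, fbar = st$fbar,
                 method = if (method == "debiased") "naive" else method,
                 ploidy = ploidy, indiv_mean_depth = indiv_depth,
                 marker_mean_depth = st$mean_depth, tau = tau_tbl)
  if (method == "debiased") {
    g <- debias_grm(g, indiv_depth, ploidy)
  }
  g
}
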