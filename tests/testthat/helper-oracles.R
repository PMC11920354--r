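# independent oracles, kept deliberately naive and dense

# generalized-least-squares solve of the GBLUP model from first principles:
# builds V = Zm (V_M x G) Zm' + Zc (V_C x I) Zc' + R densely and returns the
# mother-effect BLUP matrix (mothers x traits)
oracle_gblup <- function(data, G, vc, traits) {
  data <- as.data.frame(data)
  data$trial_year <- paste(data$trial, data$year, sep = ":")
  data$progeny_trial <- paste(data$progeny_id, data$trial, sep = ":")
  mothers <- rownames(G)
  n <- length(mothers)
  nt <- length(traits)
  obs <- do.call(rbind, lapply(seq_len(nt), function(t) {
    d <- data[!is.na(data[[traits[t]]]), ]
    data.frame(t = t, rec = d$record_id, y = d[[traits[t]]],
               m = d$mother_id, ty = d$trial_year, pt = d$progeny_trial)
  }))
  N <- nrow(obs)
  X <- NULL
  for (t in seq_len(nt)) {
    lv <- sort(unique(obs$ty[obs$t == t]))
    Xt <- matrix(0, N, length(lv))
    rows <- which(obs$t == t)
    Xt[cbind(rows, match(obs$ty[rows], lv))] <- 1
    X <- cbind(X, Xt)
  }
  pt_levels <- sort(unique(obs$pt))
  q <- length(pt_levels)
  Zm <- matrix(0, N, nt * n)
  Zm[cbind(seq_len(N), (obs$t - 1) * n + match(obs$m, mothers))] <- 1
  Zc <- matrix(0, N, nt * q)
  Zc[cbind(seq_len(N), (obs$t - 1) * q + match(obs$pt, pt_levels))] <- 1
  Sm <- kronecker(vc$V_M, G)
  Sc <- kronecker(vc$V_C, diag(q))
  R <- matrix(0, N, N)
  for (r in unique(obs$rec)) {
    rows <- which(obs$rec == r)
    R[rows, rows] <- vc$V_E[obs$t[rows], obs$t[rows], drop = FALSE]
  }
  V <- Zm %*% Sm %*% t(Zm) + Zc %*% Sc %*% t(Zc) + R
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% obs$y)
  u <- Sm %*% t(Zm) %*% Vi %*% (obs$y - X %*% b)
  matrix(u, n, nt, dimnames = list(mothers, traits))
}

# Beta-Binomial log-pmf by numerical integration of Binomial x Beta density
# (independent of the lbeta closed form used by the package)
oracle_bb_loglik <- function(tau, ra, rt, mu) {
  a <- mu * (1 - tau) / tau
  b <- (1 - mu) * (1 - tau) / tau
  keep <- rt > 0
  sum(mapply(function(x, n) {
    log(stats::integrate(function(p) {
      stats::dbinom(x, n, p) * stats::dbeta(p, a, b)
    }, 0, 1, rel.tol = 1e-12)$value)
  }, ra[keep], rt[keep]))
}

# dense grid maximiser for tau
oracle_tau_grid <- function(ra, rt, mu, step = 1e-3) {
  grid <- seq(step, 1 - step, by = step)
  ll <- vapply(grid, function(t) betabinomial_loglik(t, ra, rt, mu),
               numeric(1))
  grid[which.max(ll)]
}

# gebv tibble -> mothers x traits matrix aligned to rownames(G)
gebv_wide <- function(fit, mothers, traits) {
  m <- matrix(NA_real_, length(mothers), length(traits),
              dimnames = list(mothers, traits))
  g <- fit$gebv
  m[cbind(match(g$mother, mothers), match(g$trait, traits))] <- g$gebv
  m
}
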