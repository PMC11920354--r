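test_that("Beta-Binomial log-likelihood limits and closed form agree with oracles", {
  ra <- c(3L, 5L, 0L, 8L, 2L)
  rt <- c(10L, 8L, 0L, 12L, 6L)
  mu <- 0.45
  # tau -> 0 approaches the Binomial log-likelihood
  keep <- rt > 0
  expect_equal(betabinomial_loglik(1e-9, ra, rt, mu),
               sum(dbinom(ra[keep], rt[keep], mu, log = TRUE)),
               tolerance = 1e-6)
  expect_identical(betabinomial_loglik(0, ra, rt, mu),
                   sum(dbinom(ra[keep], rt[keep], mu, log = TRUE)))
  # a single Bernoulli draw carries no dispersion information
  for (tau in c(0, 0.2, 0.7)) {
    expect_equal(betabinomial_loglik(tau, 1L, 1L, 0.5), log(0.5))
  }
  # numerical-integration oracle for the Beta-function form
  expect_equal(betabinomial_loglik(0.3, ra, rt, mu),
               oracle_bb_loglik(0.3, ra, rt, mu), tolerance = 1e-6)
  expect_error(betabinomial_loglik(0.3, ra, rt, 1.2), "mu")
})

test_that("tau is recovered from simulated reads and matches the grid oracle", {
  set.seed(21)
  n <- 500
  rt <- rnbinom(n, mu = 40, size = 2) + 1L
  mu <- 0.5
  draw <- function(tau) {
    p <- if (tau == 0) rep(mu, n) else {
      rbeta(n, mu * (1 - tau) / tau, (1 - mu) * (1 - tau) / tau)
    }
    rbinom(n, rt, p)
  }
  ra0 <- draw(0)
  fit0 <- estimate_tau(ra0, rt, mu)
  expect_lt(fit0$tau, 0.02)
  ra3 <- draw(0.3)
  fit3 <- estimate_tau(ra3, rt, mu)
  expect_gt(fit3$tau, 0.25)
  expect_lt(fit3$tau, 0.35)
  # agreement with a dense grid search
  expect_equal(fit3$tau, oracle_tau_grid(ra3, rt, mu), tolerance = 1e-3)
  expect_equal(fit0$tau, oracle_tau_grid(ra0, rt, mu), tolerance = 1e-3)
})

test_that("heterogeneity factor follows its formula", {
  expect_equal(heterogeneity_factor(0, 10), 0.1)
  expect_equal(heterogeneity_factor(0.4, 1), 1)
  expect_equal(heterogeneity_factor(0.3, 100), 0.307)
  # decreasing in depth without overdispersion; tends to tau with it
  expect_lt(heterogeneity_factor(0, 100), heterogeneity_factor(0, 10))
  expect_equal(heterogeneity_factor(0.3, 1e8), 0.3, tolerance = 1e-6)
  expect_error(heterogeneity_factor(0.2, 0.5), "depth")
})

test_that("scaling factors match brute-force summation", {
  expect_equal(scaling_naive(0.5, 6), 0.25 / 6)
  expect_equal(scaling_naive(rep(0.5, 7), 2), 0.125 * 7)
  expect_equal(scaling_betabinomial(0.5, 100, 0.3), 0.25 * 0.307)
  set.seed(4)
  fbar <- runif(50, 0.05, 0.95)
  depth <- runif(50, 2, 120)
  tau <- runif(50, 0, 0.8)
  acc_n <- 0; acc_b <- 0
  for (j in 1:50) {
    acc_n <- acc_n + fbar[j] * (1 - fbar[j]) / 6
    acc_b <- acc_b + fbar[j] * (1 - fbar[j]) *
      (1 + (depth[j] - 1) * tau[j]) / depth[j]
  }
  expect_equal(scaling_naive(fbar, 6), acc_n)
  expect_equal(scaling_betabinomial(fbar, depth, tau), acc_b)
  # with tau = 0 and depth = k the two scalings coincide
  expect_equal(scaling_betabinomial(fbar, rep(6, 50), rep(0, 50)),
               scaling_naive(fbar, 6))
  expect_error(scaling_naive(c(1, 1), 6), "zero")
})

test_that("G is the centered cross-product over h, rows summing to zero", {
  # identical rows center to a zero matrix
  f <- matrix(0.4, 5, 3)
  g0 <- build_grm(f, h = 0.2)
  expect_true(all(g0$G == 0))

  # 3 x 2 hand computation
  f <- matrix(c(0.2, 0.5, 0.8, 1.0, 0.4, 0.1), nrow = 3,
              dimnames = list(c("a", "b", "c"), NULL))
  h <- 0.11
  fc <- sweep(f, 2, colMeans(f))
  expect_equal(build_grm(f, h = h)$G, fc %*% t(fc) / h,
               ignore_attr = "dimnames")
  expect_lt(max(abs(rowSums(build_grm(f, h = h)$G))), 1e-8 * nrow(f))

  # naive and Beta-Binomial scalings are exact scalar multiples
  cfg <- quick_cfg()
  cg <- continuous_genotypes(simulate_reads(simulate_population(cfg), cfg)) |>
    filter_markers(maf_min = 0.05, depth_min = 1, depth_max = Inf,
                   call_rate_min = 0.4)
  gn <- genomic_relationship(cg, method = "naive")
  gb <- genomic_relationship(cg, method = "betabinomial")
  expect_equal(gn$G * gn$h, gb$G * gb$h, tolerance = 1e-10)
})

test_that("debiasing scales only the diagonal by 1 - w_i", {
  cfg <- quick_cfg()
  cg <- continuous_genotypes(simulate_reads(simulate_population(cfg), cfg)) |>
    filter_markers(maf_min = 0.05, depth_min = 1, depth_max = Inf,
                   call_rate_min = 0.4)
  gn <- genomic_relationship(cg, method = "naive")
  # k = 6, depth 5 -> w = 0.5 halves the diagonal
  gd5 <- debias_grm(gn, rep(5, nrow(gn$G)), k = 6)
  expect_equal(diag(gd5$G), diag(gn$G) * 0.5)
  # infinite depth leaves G unchanged
  ginf <- debias_grm(gn, rep(1e12, nrow(gn$G)), k = 6)
  expect_equal(ginf$G, gn$G, tolerance = 1e-10)
  # mixed depths: element-by-element oracle
  set.seed(2)
  depth <- runif(nrow(gn$G), 2, 80)
  gd <- debias_grm(gn, depth, k = 6)
  for (i in seq_len(nrow(gn$G))) {
    w <- (6 - 1) / (depth[i] + 6 - 1)
    expect_equal(gd$G[i, i], gn$G[i, i] * (1 - w))
  }
  off <- upper.tri(gn$G)
  expect_identical(gd$G[off], gn$G[off])
})

test_that("summary reports diagonal means and implied inbreeding", {
  gi <- gbsblup:::new_grm(diag(4), h = 1, method = "naive")
  s <- grm_summary(gi)
  expect_equal(s$mean_diag, 1)
  expect_equal(s$mean_inbreeding, 0)
  expect_equal(s$mean_offdiag, 0)
  expect_equal(grm_summary(matrix(0, 3, 3))$mean_diag, 0)
})

test_that("an unrelated equilibrium population at high depth has mean diag near 1", {
  cfg <- sim_config(n_mothers = 100, n_markers = 500, n_families = 100,
                    tau = 0, depth_mean = 500, depth_dispersion = 1e6,
                    missing_rate = 0, seed = 31)
  genos <- simulate_population(cfg)
  # replace the half-sib dosages with Hardy-Weinberg Binomial(k, q) draws:
  # the expectation diag(G) = 1 holds for an equilibrium population without
  # shared parents
  set.seed(32)
  genos$dosage[] <- rbinom(length(genos$dosage), 6,
                           rep(genos$true_freq, each = nrow(genos$dosage)))
  cg <- continuous_genotypes(simulate_reads(genos, cfg)) |>
    filter_markers(maf_min = 0.05, depth_min = 1, depth_max = Inf,
                   call_rate_min = 0.9)
  gn <- genomic_relationship(cg, method = "naive")
  expect_equal(grm_summary(gn)$mean_diag, 1, tolerance = 0.1)
})

test_that("overdispersed reads order the mean diagonals naive >= debiased >= betabinomial", {
  cfg <- sim_config(n_mothers = 80, n_markers = 400, n_families = 8,
                    depth_mean = 40, missing_rate = 0.1, seed = 33)
  genos <- simulate_population(cfg)
  cg <- continuous_genotypes(simulate_reads(genos, cfg)) |>
    filter_markers(maf_min = 0.05, depth_min = 5, depth_max = 300,
                   call_rate_min = 0.5)
  d_n <- grm_summary(genomic_relationship(cg, method = "naive"))$mean_diag
  d_d <- grm_summary(genomic_relationship(cg, method = "debiased"))$mean_diag
  d_b <- grm_summary(genomic_relationship(cg,
                                          method = "betabinomial"))$mean_diag
  expect_gte(d_n, d_d)
  expect_gte(d_d, d_b)
  # tau and omega track each other across markers at this depth
  tt <- genomic_relationship(cg, method = "betabinomial")$tau
  expect_gt(cor(tt$tau, tt$omega, use = "complete.obs"), 0.9)
})
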