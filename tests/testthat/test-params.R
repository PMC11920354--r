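test_that("heritability reproduces the published worked examples", {
  # first-cut yield: components in (kg DM/ha)^2, mean diag(G) = 1.26
  expect_equal(round(heritability(sigma2_A = 60342.8, sigma2_C = 79075.3,
                                  sigma2_e = 482725.8, mean_diag_G = 1.26),
                     2), 0.13)
  expect_equal(round(heritability(sigma2_A = 102520.8, sigma2_C = 29488.8,
                                  sigma2_e = 179893.3, mean_diag_G = 1.26),
                     2), 0.53)
  expect_equal(round(heritability(sigma2_A = 21229.6, sigma2_C = 11370.6,
                                  sigma2_e = 82912.9, mean_diag_G = 1.26),
                     2), 0.26)
  expect_equal(round(heritability(sigma2_A = 6.60, sigma2_C = 5.88,
                                  sigma2_e = 35.44, mean_diag_G = 1.26),
                     2), 0.19)
  # second-cut digestibility, mother-scale input
  expect_equal(round(heritability(sigma2_M = 0.31, sigma2_C = 0.10,
                                  sigma2_e = 1.32, mean_diag_G = 1.26),
                     2), 0.86)
  # the formula is not clamped: no non-genetic variance gives 4
  expect_equal(heritability(sigma2_M = 5, sigma2_C = 0, sigma2_e = 0,
                            mean_diag_G = 1), 4)
  expect_error(heritability(sigma2_M = 0, sigma2_C = 0, sigma2_e = 0,
                            mean_diag_G = 1), "denominator")
  expect_error(heritability(sigma2_M = 1, sigma2_A = 4, sigma2_C = 0,
                            sigma2_e = 1, mean_diag_G = 1), "exactly one")
})

test_that("repeatability shares the heritability denominator", {
  expect_equal(round(repeatability(sigma2_M = 15085.7, sigma2_C = 79075.3,
                                   sigma2_e = 482725.8, mean_diag_G = 1.26),
                     2), 0.27)
  expect_equal(round(repeatability(sigma2_A = 102520.8, sigma2_C = 29488.8,
                                   sigma2_e = 179893.3, mean_diag_G = 1.26),
                     2), 0.66)
  # sigma2_C = 0 collapses c2 onto h2
  expect_equal(repeatability(sigma2_M = 2, sigma2_C = 0, sigma2_e = 5,
                             mean_diag_G = 1.2),
               heritability(sigma2_M = 2, sigma2_C = 0, sigma2_e = 5,
                            mean_diag_G = 1.2))
  # c2 - h2 is exactly sigma2_C / denominator
  h <- heritability(sigma2_M = 3, sigma2_C = 4, sigma2_e = 9,
                    mean_diag_G = 1.1)
  c2 <- repeatability(sigma2_M = 3, sigma2_C = 4, sigma2_e = 9,
                      mean_diag_G = 1.1)
  expect_equal(c2 - h, 4 / (3 * 1.1 + 4 + 9))
  expect_gte(c2, h)
})

test_that("genetic correlations reproduce the published mother-level examples", {
  # mother-level covariances with additive variances 4x the mother variances
  vm_y1 <- 60342.8 / 4; vm_wd <- 6.60 / 4
  VM <- matrix(c(vm_y1, -114.3, -114.3, vm_wd), 2)
  expect_equal(round(genetic_correlations(VM)[1, 2], 2), -0.72)
  VM2 <- matrix(c(0.72 / 4, 0.14, 0.14, 1.24 / 4), 2)
  expect_equal(round(genetic_correlations(VM2)[1, 2], 2), 0.59)
  VM3 <- matrix(c(102520.8 / 4, 5256.7, 5256.7, 21229.6 / 4), 2)
  expect_equal(round(genetic_correlations(VM3)[1, 2], 2), 0.45)
  # unit diagonal and scale invariance
  expect_equal(diag(genetic_correlations(VM)), c(1, 1))
  expect_equal(genetic_correlations(VM * 17.3), genetic_correlations(VM))
  expect_error(genetic_correlations(matrix(c(0, 0, 0, 1), 2)), "zero")
})

test_that("phenotypic correlations follow V_P = V_M + V_C + V_E", {
  VM <- matrix(c(2, 0.5, 0.5, 1), 2)
  # with V_C = V_E = 0 they equal the mother-level correlations
  z <- matrix(0, 2, 2)
  expect_equal(phenotypic_correlations(VM, z, z), cov2cor(VM))
  # diagonal inputs give the identity
  expect_equal(phenotypic_correlations(diag(2), diag(2), diag(2)), diag(2))
  # random PSD triple against a direct covariance-to-correlation oracle
  set.seed(11)
  rpsd <- function() { a <- matrix(rnorm(9), 3); crossprod(a) }
  A <- rpsd(); B <- rpsd(); C <- rpsd()
  S <- A + B + C
  oracle <- S / sqrt(diag(S) %o% diag(S))
  expect_equal(phenotypic_correlations(A, B, C), oracle)
})

test_that("genetic_params assembles the full report", {
  VM <- matrix(c(4, 1, 1, 3), 2, dimnames = list(c("a", "b"), c("a", "b")))
  vc <- variance_components(VM, diag(c(2, 1)), diag(c(10, 7)), c("a", "b"))
  gp <- genetic_params(vc, mean_diag_G = 1.26)
  expect_equal(gp$params$h2,
               heritability(sigma2_M = c(4, 3), sigma2_C = c(2, 1),
                            sigma2_e = c(10, 7), mean_diag_G = 1.26),
               ignore_attr = TRUE)
  expect_equal(gp$params$sigma2_A, c(16, 12), ignore_attr = TRUE)
  expect_true(all(is.na(gp$params$h2_se)))
  pt <- param_table(gp)
  expect_equal(diag(pt), round(gp$params$h2, 2), ignore_attr = TRUE)
  expect_equal(pt[2, 1], round(gp$r_A[2, 1], 2), ignore_attr = TRUE)
  expect_equal(pt[1, 2], round(gp$r_P[1, 2], 2), ignore_attr = TRUE)
  expect_named(tidy(gp), c("trait", "sigma2_M", "sigma2_A", "sigma2_C",
                           "sigma2_e", "h2", "c2", "h2_se", "c2_se"))
})

test_that("display rounding is half away from zero", {
  expect_equal(gbsblup:::round_half_up(0.125, 2), 0.13)
  expect_equal(gbsblup:::round_half_up(-0.125, 2), -0.13)
  expect_equal(gbsblup:::round_half_up(0.7245, 2), 0.72)
})
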