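toy_records <- function(mothers, years = 2001) {
  tibble::tibble(
    record_id = paste0("r", seq_along(mothers)),
    mother_id = mothers,
    progeny_id = paste0("p", seq_along(mothers)),
    trial = "T1", year = rep_len(years, length(mothers)),
    y = seq_along(mothers) * 1.0
  ) |> trait_data("y")
}

test_that("family splits respect the size floor and partition when floor is 1", {
  mothers <- c(paste0("A", 1:60), paste0("B", 1:55), paste0("C", 1:10))
  fam <- tibble::tibble(
    mother = mothers,
    family = rep(c("famA", "famB", "famC"), c(60, 55, 10))
  )
  data <- toy_records(mothers)
  splits <- family_cv_splits(data, fam, min_family_size = 50)
  expect_length(splits, 2)
  expect_equal(purrr::map_chr(splits, "label"), c("famA", "famB"))

  all_splits <- family_cv_splits(data, fam, min_family_size = 1)
  expect_length(all_splits, 3)
  val_ids <- sort(unlist(purrr::map(all_splits, "val_records")))
  expect_equal(val_ids, sort(data$record_id))  # validation sets partition

  expect_error(family_cv_splits(data, fam, min_family_size = 100),
               "family sizes")
})

test_that("a synthetic 18-family map yields 18 evaluations", {
  mothers <- sprintf("M%04d", 1:950)
  fam <- tibble::tibble(mother = mothers,
                        family = sprintf("F%02d", rep(1:18, c(rep(53, 17),
                                                              49)) ))
  data <- toy_records(mothers)
  splits <- family_cv_splits(data, fam, min_family_size = 50)
  expect_length(splits, 17)  # the 49-mother family misses the floor
  fam$family[fam$mother == "M0950"] <- "F18"
  fam$family[1:4] <- "F18"
  splits <- family_cv_splits(data, fam, min_family_size = 49)
  expect_length(splits, 18)
})

test_that("forward splits cut on year and count validation-only mothers", {
  data <- tibble::tibble(
    record_id = paste0("r", 1:10),
    mother_id = c(rep("m1", 4), rep("m2", 3), rep("m3", 3)),
    progeny_id = paste0("p", 1:10),
    trial = "T1",
    year = c(2001:2004, 2002:2004, 2005, 2005, 2005),
    y = rnorm(10)
  ) |> trait_data("y")
  sp <- forward_split(data, 2004)
  expect_equal(sort(sp$val_records),
               sort(data$record_id[data$year >= 2004]))
  expect_equal(length(sp$est_records) + length(sp$val_records), 10L)
  expect_equal(sp$meta$n_new_mothers, 1L)  # m3 has records only from 2005
  expect_error(forward_split(data, 2040), "cutoff_year")
  expect_error(forward_split(data, 1999), "cutoff_year")
})

test_that("adjusted progeny means subtract fitted fixed and PE effects", {
  pr_cfg <- sim_config(n_mothers = 20, n_markers = 100, n_families = 2,
                       V_M = matrix(3), V_C = matrix(2), V_E = matrix(6),
                       n_years = 6, progeny_per_mother = 2,
                       records_per_progeny = 2, seed = 71)
  genos <- simulate_population(pr_cfg)
  G <- dosage_grm(genos) + diag(0.05, 20)
  phen <- simulate_phenotypes(genos, G, pr_cfg)
  vc <- variance_components(matrix(3), matrix(2), matrix(6), "t1")
  data <- trait_data(phen$data, "t1")
  fit <- solve_gblup(data, G, vc)
  adj <- adjusted_progeny_means(data, fit)
  # hand-computed residual means for one mother
  m <- adj$mother[1]
  d <- data[data$mother_id == m, ]
  fx <- fit$fixef$estimate[match(d$trial_year, fit$fixef$trial_year)]
  pe <- fit$pe$estimate[match(d$progeny_trial, fit$pe$progeny_trial)]
  expect_equal(adj$adj_mean[1], mean(d$t1 - fx - pe))

  # shifting every record by a constant moves the fixed effects, not the
  # adjusted means
  data2 <- data
  data2$t1 <- data2$t1 + 500
  fit2 <- solve_gblup(data2, G, vc)
  adj2 <- adjusted_progeny_means(data2, fit2)
  expect_equal(adj2$adj_mean, adj$adj_mean, tolerance = 1e-6)

  # unknown trial-year levels are dropped with a warning
  stray <- data[1, ]
  stray$record_id <- "weird"
  stray$trial <- "T999"
  expect_warning(adjusted_progeny_means(rbind(data[2:5, ], stray), fit),
                 "not in fit")
})

test_that("predictive ability is a guarded correlation", {
  x <- c(1, 2, 3, 4)
  expect_equal(predictive_ability(x, x), 1)
  expect_equal(predictive_ability(x, -x), -1)
  set.seed(3)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(predictive_ability(a, b), cor(a, b))
  # invariant to positive affine transforms
  expect_equal(predictive_ability(2 * a + 5, b), predictive_ability(a, b))
  expect_warning(out <- predictive_ability(rep(1, 5), rnorm(5)),
                 "zero variance")
  expect_true(is.na(out))
  expect_warning(out2 <- predictive_ability(c(1, 2), c(1, 2)), "fewer")
  expect_true(is.na(out2))
})

test_that("LR statistics match their least-squares definition", {
  x <- rnorm(40)
  expect_equal(unlist(lr_statistics(x, x)[c("correlation", "slope", "r2")]),
               c(correlation = 1, slope = 1, r2 = 1))
  s <- lr_statistics(2 * x, x)
  expect_equal(s$correlation, 1)
  expect_equal(s$slope, 2)
  expect_equal(s$r2, 1)
  set.seed(4)
  full <- rnorm(50); red <- 0.8 * full + rnorm(50, sd = 0.4)
  s2 <- lr_statistics(full, red)
  expect_equal(s2$slope, cov(full, red) / var(red))  # normal-equation oracle
  expect_equal(s2$r2, cor(full, red)^2)
  expect_equal(s2$n, 50L)
  expect_warning(out <- lr_statistics(full, rep(1, 50)), "slope undefined")
  expect_true(is.na(out$slope))
})

test_that("higher heritability raises predictive ability", {
  run_pa <- function(vm) {
    cfg <- sim_config(n_mothers = 120, n_markers = 200, n_families = 6,
                      V_M = matrix(vm), V_C = matrix(1), V_E = matrix(10),
                      n_years = 8, progeny_per_mother = 2,
                      records_per_progeny = 2, seed = 73)
    genos <- simulate_population(cfg)
    G <- dosage_grm(genos) + diag(0.05, 120)
    phen <- simulate_phenotypes(genos, G, cfg)
    vc <- variance_components(matrix(vm), matrix(1), matrix(10), "t1")
    data <- trait_data(phen$data, "t1")
    sp <- forward_split(data, 2006)
    rep <- run_validation(data, G, vc, sp, mode = "single")
    rep$predictive_ability
  }
  pa_low <- run_pa(0.3)
  pa_high <- run_pa(12)
  expect_gt(pa_high, pa_low)
  expect_gt(pa_high, 0.4)
})
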