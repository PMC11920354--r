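test_that("VCF allelic depths round-trip the enumerated fixture", {
  path <- write_fixture_vcf(tempfile(fileext = ".vcf"))
  rd <- suppressMessages(read_vcf_depths(path))
  expect_equal(rd$ra, fixture_ra())
  expect_equal(rd$rb, fixture_rb())
  # one tri-allelic and one depth-less record skipped, with counts logged
  expect_equal(sum(rd$skipped$n), 2L)
  expect_setequal(rd$skipped$reason,
                  c("multiallelic_or_not_snp", "no_depth_field"))
})

test_that("an empty VCF body yields an empty matrix, not an error", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"x\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2"
  ), path)
  rd <- read_vcf_depths(path)
  expect_equal(dim(rd$ra), c(2L, 0L))
})

test_that("continuous genotypes follow f = RA/(RA+RB) with zero reads missing", {
  ra <- matrix(c(3L, 0L, 5L), 1)
  rb <- matrix(c(1L, 0L, 0L), 1)
  dimnames(ra) <- dimnames(rb) <- list("i1", c("a", "b", "c"))
  cg <- cg_from_counts(ra, rb)
  expect_equal(as.numeric(cg$f), c(0.75, NA, 1))
})

test_that("repeated samples merge by averaging observed frequencies", {
  ra <- matrix(c(5L, 7L,   0L, 4L,  3L, 0L), nrow = 2,
               dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  rb <- matrix(c(5L, 3L,   0L, 6L,  3L, 0L), nrow = 2,
               dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  cg <- cg_from_counts(ra, rb)
  merged <- merge_repeated_samples(
    cg, data.frame(sample = c("s1", "s2"), individual = "ind")
  )
  expect_equal(nrow(merged$f), 1L)
  expect_equal(as.numeric(merged$f), c(mean(c(0.5, 0.7)), 0.4, 0.5))
  # reads summed for downstream depth statistics
  expect_equal(as.numeric(merged$rt), c(20L, 10L, 6L))

  # single-sample individuals pass through unchanged
  single <- merge_repeated_samples(
    cg, data.frame(sample = c("s1", "s2"), individual = c("i1", "i2"))
  )
  expect_equal(single$f, cg$f, ignore_attr = "dimnames")

  expect_error(
    merge_repeated_samples(cg, data.frame(sample = "s1", individual = "i1")),
    "s2"
  )
})

test_that("marker filtering matches hand enumeration on a 10-marker toy", {
  # 4 individuals x 10 markers; depth 0 encodes missing
  set.seed(1)
  n <- 4; m <- 10
  rt <- matrix(20L, n, m, dimnames = list(paste0("i", 1:n), paste0("m", 1:m)))
  rt[, 2] <- 300L                      # mean depth 300 > max
  rt[, 3] <- 4L                        # mean depth 4 < min
  rt[1:2, 4] <- 0L                     # call rate 0.5
  rt[1, 5] <- 0L                       # call rate 0.75
  frac <- matrix(0.5, n, m)
  frac[, 6] <- 0.98                    # fails MAF
  frac[, 7] <- 0.02                    # fails MAF
  ra <- matrix(as.integer(round(rt * frac)), n, m, dimnames = dimnames(rt))
  cg <- cg_from_counts(ra, rt - ra)
  out <- filter_markers(cg, maf_min = 0.05, depth_min = 10, depth_max = 200,
                        call_rate_min = 0.7)
  expect_setequal(colnames(out$f), c("m1", "m5", "m8", "m9", "m10"))
  expect_equal(out$filter_log$markers, c(10L, 8L, 6L, 5L))

  # conjunctive criteria: pairwise intersection of single-criterion runs
  # equals the combined run
  only <- function(...) colnames(filter_markers(cg, ...)$f)
  a <- only(maf_min = 0.05, depth_min = 0, depth_max = Inf,
            call_rate_min = 1e-9)
  b <- only(maf_min = 0, depth_min = 10, depth_max = 200,
            call_rate_min = 1e-9)
  cc <- only(maf_min = 0, depth_min = 0, depth_max = Inf,
             call_rate_min = 0.7)
  expect_setequal(Reduce(intersect, list(a, b, cc)), colnames(out$f))

  expect_error(filter_markers(cg, maf_min = 0.5, depth_min = 1e5,
                              depth_max = 2e5, call_rate_min = 1),
               "attrition")
})

test_that("imputation fills with the marker mean and preserves column means", {
  ra <- matrix(c(2L, 4L, 0L,  5L, 5L, 5L), nrow = 3,
               dimnames = list(paste0("i", 1:3), c("a", "b")))
  rt <- matrix(c(10L, 10L, 0L,  10L, 10L, 10L), nrow = 3,
               dimnames = dimnames(ra))
  cg <- cg_from_counts(ra, rt - ra)
  out <- impute_missing(cg)
  expect_equal(out$f[3, "a"], 0.3)  # mean of 0.2 and 0.4
  expect_false(any(is.na(out$f)))

  # fully observed input passes through identically
  full <- cg_from_counts(matrix(3L, 2, 2), matrix(5L, 2, 2))
  expect_equal(impute_missing(full)$f, full$f)

  # random missingness: per-marker means unchanged
  set.seed(7)
  rt2 <- matrix(10L, 20, 8)
  ra2 <- matrix(rbinom(160, 10, 0.4), 20, 8)
  rt2[matrix(runif(160) < 0.2, 20, 8)] <- 0L
  ra2[rt2 == 0] <- 0L
  cg2 <- cg_from_counts(ra2, rt2 - ra2)
  before <- marker_stats(cg2)$fbar
  after <- colMeans(impute_missing(cg2)$f)
  expect_equal(after, before, ignore_attr = TRUE)
})

test_that("high-depth Binomial reads recover dosage/k", {
  cfg <- sim_config(n_mothers = 30, n_markers = 50, n_families = 3,
                    tau = 0, depth_mean = 4000, depth_dispersion = 1e6,
                    missing_rate = 0, seed = 12)
  genos <- simulate_population(cfg)
  cg <- continuous_genotypes(simulate_reads(genos, cfg))
  expect_lt(max(abs(cg$f - genos$dosage / 6)), 3 / sqrt(3000))
})
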