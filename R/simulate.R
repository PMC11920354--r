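#' Simulation configuration for hexaploid GBS data
#'
#' Bundles and validates every knob of the synthetic-data generator: the
#' mother-clone population (half-sib families, hexaploid dosages), the
#' sequencing process (Beta-Binomial read counts over a right-skewed,
#' zero-inflated negative-binomial depth distribution), and the phenotype
#' model (trial-by-year fixed effects, mother genetic effects with
#' relationship matrix G, progeny-within-trial permanent-environment
#' effects, multi-trait residuals).
#'
#' Defaults emulate a timothy-like GBS population: ploidy 6; base
#' reference-allele frequencies drawn from Beta(2.64, 0.79) (mean 0.77,
#' SD 0.20); per-marker overdispersion tau drawn from Beta(1.3, 3.7)
#' (mean 0.26, SD about 0.16); total read depth zero-inflated negative
#' binomial with mean 38 and dispersion (size) 1.4 (mean 37.9, SD 33 when
#' non-missing); 18 half-sib families; and single-trait variance components
#' of first-cut yield magnitude (mother 15085.7, permanent environment
#' 79075.3, residual 482725.8, in (kg DM/ha)^2).
#'
#' @param n_mothers Number of genotyped mother clones.
#' @param n_markers Number of biallelic SNP markers.
#' @param n_families Number of half-sib families (must not exceed
#'   `n_mothers`).
#' @param ploidy Ploidy `k` (6 for hexaploid timothy).
#' @param true_freq Optional vector of per-marker base allele frequencies in
#'   `[0, 1]` (recycled); when `NULL`, drawn from `Beta(freq_shape)`.
#' @param freq_shape Length-2 shape parameters of the Beta distribution for
#'   base allele frequencies.
#' @param tau Per-marker overdispersion in `[0, 1)`: a scalar, a vector of
#'   length `n_markers`, or `NULL` to draw from `Beta(tau_shape)`.
#' @param tau_shape Length-2 shape parameters of the Beta draw for tau.
#' @param depth_mean,depth_dispersion Mean and size (dispersion) of the
#'   negative-binomial total read depth.
#' @param missing_rate Probability that a sample x marker cell yields zero
#'   reads in addition to negative-binomial zeros (locus dropout).
#' @param replicated_mothers Number of mothers genotyped as repeated samples.
#' @param replicates Samples per replicated mother (2--5).
#' @param V_M,V_C,V_E Trait x trait mother, permanent-environment, and
#'   residual covariance matrices (symmetric PSD, equal dimensions).
#' @param trait_names Trait labels; defaults to `"t1"`, ... matching `V_M`.
#' @param n_years Number of recording years (years run `2001 ...`).
#' @param trials_per_year Trials starting in each year.
#' @param n_locations Number of trial locations.
#' @param progeny_per_mother Progeny lines recorded per mother.
#' @param records_per_progeny Repeated records per progeny within its trial
#'   (consecutive years); values `>= 2` let permanent-environment and
#'   residual variance separate.
#' @param fixed_sd Per-trait SD of trial-by-year fixed effects; defaults to
#'   `0.5 * sqrt(diag(V_E))`.
#' @param trait_missing_rate Per-trait probability that a record lacks a
#'   trait value (missing completely at random).
#' @param ridge Ridge added to a singular relationship matrix before
#'   factorisation in [simulate_phenotypes()].
#' @param seed Integer seed; fixing it makes all three simulation stages
#'   bit-reproducible.
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_population()], [simulate_reads()],
#'   [simulate_phenotypes()], [simulate_dataset()]
#' @export
sim_config <- function(n_mothers = 300,
                       n_markers = 1000,
                       n_families = 18,
                       ploidy = 6,
                       true_freq = NULL,
                       freq_shape = c(2.64, 0.79),
                       tau = NULL,
                       tau_shape = c(1.3, 3.7),
                       depth_mean = 38,
                       depth_dispersion = 1.4,
                       missing_rate = 0.2,
                       replicated_mothers = 0,
                       replicates = 2,
                       V_M = matrix(15085.7),
                       V_C = matrix(79075.3),
                       V_E = matrix(482725.8),
                       trait_names = NULL,
                       n_years = 10,
                       trials_per_year = 3,
                       n_locations = 4,
                       progeny_per_mother = 2,
                       records_per_progeny = 3,
                       fixed_sd = NULL,
                       trait_missing_rate = 0,
                       ridge = 1e-6,
                       seed = NULL) {
  cfg <- as.list(environment())
  if (cfg$n_families > cfg$n_mothers) {
    abort("`n_families` must not exceed `n_mothers`.")
  }
  if (cfg$ploidy < 2) abort("`ploidy` must be at least 2.")
  for (nm in c("V_M", "V_C", "V_E")) {
    m <- cfg[[nm]]
    if (!is.matrix(m)) m <- as.matrix(m)
    assert_psd(m, nm)
    cfg[[nm]] <- m
  }
  dims <- vapply(cfg[c("V_M", "V_C", "V_E")], nrow, integer(1))
  if (length(unique(dims)) != 1L) {
    abort("`V_M`, `V_C` and `V_E` must have identical dimensions.")
  }
  n_traits <- dims[[1]]
  if (is.null(cfg$trait_names)) cfg$trait_names <- paste0("t", seq_len(n_traits))
  if (length(cfg$trait_names) != n_traits) {
    abort("`trait_names` must match the dimension of `V_M`.")
  }
  if (!is.null(cfg$tau)) {
    if (any(cfg$tau < 0 | cfg$tau >= 1)) abort("`tau` values must lie in [0, 1).")
  }
  if (!is.null(cfg$true_freq)) {
    if (any(cfg$true_freq < 0 | cfg$true_freq > 1)) {
      abort("`true_freq` values must lie in [0, 1].")
    }
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    abort("`missing_rate` must lie in [0, 1).")
  }
  if (is.null(cfg$fixed_sd)) cfg$fixed_sd <- 0.5 * sqrt(diag(cfg$V_E))
  cfg$fixed_sd <- rep_len(cfg$fixed_sd, n_traits)
  if (cfg$replicates < 2 || cfg$replicates > 5) {
    abort("`replicates` must be between 2 and 5.")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a half-sib mother-clone population
#'
#' Draws hexaploid allele dosages for `n_mothers` individuals grouped into
#' half-sib families. Each family shares one simulated parent: an
#' individual's dosage at marker j is the sum of `floor(k/2)` gametes drawn
#' at the family parent's realised allele frequency and the remaining
#' gametes drawn at the population base frequency, so half-sibs are more
#' related than non-sibs while marginal frequencies stay at the base level.
#'
#' @param config A [sim_config()].
#' @return An object of class `true_genotypes`: a list with `dosage`
#'   (mothers x markers integer matrix in `0..k`), `ploidy`, `true_freq`,
#'   and `families` (tibble with columns `mother`, `family`).
#' @examples
#' genos <- simulate_population(sim_config(n_mothers = 40, n_markers = 50,
#'                                         n_families = 4, seed = 1))
#' range(genos$dosage)
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_mothers
  m <- config$n_markers
  k <- config$ploidy
  q <- if (is.null(config$true_freq)) {
    rbeta(m, config$freq_shape[1], config$freq_shape[2])
  } else {
    rep_len(config$true_freq, m)
  }
  fam_sizes <- table(rep_len(seq_len(config$n_families), n))
  fam <- rep(seq_len(config$n_families), fam_sizes)
  fam_lab <- sprintf("F%02d", fam)
  mothers <- sprintf("M%04d", seq_len(n))
  markers <- sprintf("snp%05d", seq_len(m))

  k_shared <- k %/% 2
  k_own <- k - k_shared
  # realised parent frequency per family x marker
  parent_freq <- matrix(
    rbinom(config$n_families * m, k, rep(q, each = config$n_families)) / k,
    nrow = config$n_families
  )
  shared <- matrix(
    rbinom(n * m, k_shared, parent_freq[fam, , drop = FALSE]),
    nrow = n
  )
  own <- matrix(rbinom(n * m, k_own, rep(q, each = n)), nrow = n)
  dosage <- shared + own
  dimnames(dosage) <- list(mothers, markers)
  structure(
    list(
      dosage = dosage,
      ploidy = k,
      true_freq = setNames(q, markers),
      families = tibble::tibble(mother = mothers, family = fam_lab)
    ),
    class = "true_genotypes"
  )
}

#' Simulate GBS read counts under the Beta-Binomial hierarchy
#'
#' For every sample x marker cell, a total read depth `R_T` is drawn from a
#' zero-inflated negative binomial (zero total depth encodes a missing
#' marker). Given a dosage `d` and ploidy `k`, the latent per-individual
#' allele sampling probability is `p ~ Beta(mu, tau)` in the
#' location/dispersion parameterisation with `mu = d/k`
#' (`alpha = mu(1-tau)/tau`, `beta = (1-mu)(1-tau)/tau`), and the reference
#' read count is `R_A ~ Binomial(R_T, p)`. `tau = 0` (and the degenerate
#' means `mu` of 0 or 1) collapse to pure Binomial sampling with `p = mu`.
#'
#' When `config$replicated_mothers > 0` the first mothers are sequenced as
#' several independent samples, mimicking repeated genotyping.
#'
#' @param genos A [true_genotypes][simulate_population()] object.
#' @param config The same [sim_config()] used to generate `genos`.
#' @return An object of class `read_depths` with integer matrices `ra`
#'   (reference) and `rb` (alternate) of dimension samples x markers, a
#'   `sample_map` tibble (`sample`, `individual`), and the per-marker
#'   `tau_true` used.
#' @export
simulate_reads <- function(genos, config) {
  stopifnot(inherits(genos, "true_genotypes"), inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  k <- genos$ploidy
  mothers <- rownames(genos$dosage)
  m <- ncol(genos$dosage)

  reps <- rep(1L, length(mothers))
  if (config$replicated_mothers > 0) {
    reps[seq_len(min(config$replicated_mothers, length(mothers)))] <-
      as.integer(config$replicates)
  }
  owner <- rep(seq_along(mothers), reps)
  samples <- sprintf("S%04d", seq_along(owner))
  sample_map <- tibble::tibble(sample = samples, individual = mothers[owner])

  tau <- config$tau
  tau <- if (is.null(tau)) {
    rbeta(m, config$tau_shape[1], config$tau_shape[2])
  } else {
    rep_len(tau, m)
  }
  names(tau) <- colnames(genos$dosage)

  ns <- length(samples)
  rt <- matrix(
    rnbinom(ns * m, mu = config$depth_mean, size = config$depth_dispersion),
    nrow = ns
  )
  if (config$missing_rate > 0) {
    rt[runif(ns * m) < config$missing_rate] <- 0L
  }
  mu <- genos$dosage[owner, , drop = FALSE] / k
  tau_m <- matrix(tau, nrow = ns, ncol = m, byrow = TRUE)
  p <- mu
  inner <- tau_m > 0 & mu > 0 & mu < 1
  if (any(inner)) {
    a <- mu[inner] * (1 - tau_m[inner]) / tau_m[inner]
    b <- (1 - mu[inner]) * (1 - tau_m[inner]) / tau_m[inner]
    p[inner] <- rbeta(sum(inner), a, b)
  }
  ra <- matrix(rbinom(ns * m, rt, p), nrow = ns)
  dimnames(ra) <- dimnames(rt) <- list(samples, colnames(genos$dosage))
  new_read_depths(ra = ra, rb = rt - ra, sample_map = sample_map,
                  tau_true = tau)
}

#' Relationship matrix from true dosages
#'
#' VanRaden-style relationship matrix computed from the simulated (noise
#' free) dosages, used as the generative G when simulating phenotypes so
#' that true breeding values are consistent with the population structure.
#'
#' @param genos A [true_genotypes][simulate_population()] object.
#' @return A numeric mothers x mothers matrix.
#' @export
dosage_grm <- function(genos) {
  stopifnot(inherits(genos, "true_genotypes"))
  f <- genos$dosage / genos$ploidy
  fbar <- colMeans(f)
  keep <- fbar > 0 & fbar < 1
  f <- f[, keep, drop = FALSE]
  fbar <- fbar[keep]
  h <- sum(fbar * (1 - fbar)) / genos$ploidy
  fc <- sweep(f, 2, fbar)
  tcrossprod(fc) / h
}

#' Simulate multi-trait phenotypes with trial structure
#'
#' Draws mother genetic effects from a matrix normal with row covariance `G`
#' and column covariance `V_M`, progeny-within-trial permanent-environment
#' effects from `V_C`, residuals from `V_E`, and adds trial-by-year fixed
#' effects. Each mother contributes `progeny_per_mother` progeny; each
#' progeny is assigned to one trial (a location x start-year combination)
#' and recorded in `records_per_progeny` consecutive years.
#'
#' @param genos A [true_genotypes][simulate_population()] object.
#' @param grm A relationship matrix for the mothers: a [genomic_relationship()]
#'   object, or a plain matrix (e.g. [dosage_grm()] output or an identity).
#' @param config The [sim_config()].
#' @return A list of class `sim_phenotypes` with `data` (a tibble of records
#'   with columns `record_id`, `mother_id`, `progeny_id`, `trial`, `year`,
#'   `location`, and one column per trait), `gebv_true` (tibble `mother`,
#'   `trait`, `gebv_true`), and `fixed_true` (tibble of the trial-by-year
#'   effects used).
#' @export
simulate_phenotypes <- function(genos, grm, config) {
  stopifnot(inherits(genos, "true_genotypes"), inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed + 2L)
  G <- if (inherits(grm, "grm")) grm$G else as.matrix(grm)
  mothers <- rownames(genos$dosage)
  n <- length(mothers)
  if (nrow(G) != n) abort("`grm` dimension does not match the mother count.")
  traits <- config$trait_names
  nt <- length(traits)

  # mother effects: rows ~ G, columns ~ V_M
  if (all(config$V_M == 0)) {
    m_eff <- matrix(0, n, nt)
  } else {
    L <- chol_ridge(G, config$ridge)
    m_eff <- t(L) %*% matrix(rnorm(n * nt), n, nt) %*% t(psd_sqrt(config$V_M))
  }
  dimnames(m_eff) <- list(mothers, traits)

  # trial layout: trials_per_year trials start each usable year
  years <- 2000L + seq_len(config$n_years)
  start_years <- years[years <= max(years) - config$records_per_progeny + 1L]
  if (length(start_years) == 0L) {
    abort("`n_years` too small for `records_per_progeny`.")
  }
  trial_tbl <- tidyr::expand_grid(start = start_years,
                                  idx = seq_len(config$trials_per_year))
  trial_tbl$trial <- sprintf("T%03d", seq_len(nrow(trial_tbl)))
  trial_tbl$location <- sprintf(
    "L%02d", 1L + (seq_len(nrow(trial_tbl)) - 1L) %% config$n_locations
  )

  prog <- tidyr::expand_grid(mother_id = mothers,
                             p = seq_len(config$progeny_per_mother))
  prog$progeny_id <- sprintf("P%05d", seq_len(nrow(prog)))
  prog$trial_row <- sample.int(nrow(trial_tbl), nrow(prog), replace = TRUE)

  rec <- tidyr::expand_grid(prog, r = seq_len(config$records_per_progeny))
  rec$trial <- trial_tbl$trial[rec$trial_row]
  rec$location <- trial_tbl$location[rec$trial_row]
  rec$year <- trial_tbl$start[rec$trial_row] + rec$r - 1L
  rec$record_id <- sprintf("R%06d", seq_len(nrow(rec)))

  ty <- paste(rec$trial, rec$year, sep = ":")
  ty_levels <- sort(unique(ty))
  fixed <- matrix(rnorm(length(ty_levels) * nt), length(ty_levels), nt)
  fixed <- sweep(fixed, 2, config$fixed_sd, `*`)
  dimnames(fixed) <- list(ty_levels, traits)

  pe_levels <- sort(unique(paste(rec$progeny_id, rec$trial, sep = ":")))
  pe <- matrix(rnorm(length(pe_levels) * nt), length(pe_levels), nt) %*%
    t(psd_sqrt(config$V_C))
  rownames(pe) <- pe_levels

  e <- matrix(rnorm(nrow(rec) * nt), nrow(rec), nt) %*% t(psd_sqrt(config$V_E))

  y <- fixed[ty, , drop = FALSE] +
    m_eff[rec$mother_id, , drop = FALSE] +
    pe[paste(rec$progeny_id, rec$trial, sep = ":"), , drop = FALSE] +
    e
  colnames(y) <- traits
  if (config$trait_missing_rate > 0) {
    y[matrix(runif(length(y)) < config$trait_missing_rate, nrow(y))] <- NA_real_
  }

  data <- tibble::tibble(
    record_id = rec$record_id,
    mother_id = rec$mother_id,
    progeny_id = rec$progeny_id,
    trial = rec$trial,
    year = rec$year,
    location = rec$location
  )
  data <- dplyr::bind_cols(data, tibble::as_tibble(y))

  gebv_true <- tibble::as_tibble(m_eff, rownames = "mother") |>
    tidyr::pivot_longer(-"mother", names_to = "trait",
                        values_to = "gebv_true")
  structure(
    list(
      data = data,
      gebv_true = gebv_true,
      fixed_true = tibble::as_tibble(fixed, rownames = "trial_year")
    ),
    class = "sim_phenotypes"
  )
}

#' Simulate a complete dataset (population, reads, phenotypes)
#'
#' Convenience wrapper chaining [simulate_population()], [simulate_reads()],
#' [dosage_grm()] and [simulate_phenotypes()]; optionally writes the VCF,
#' phenotype table, and sample map so the file-based pipeline can be
#' exercised end to end.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory for `reads.vcf`, `phenotypes.tsv`,
#'   and `sample_map.tsv`.
#' @return A list with `genos`, `reads`, `G_true`, `phenotypes`, and (when
#'   `dir` is given) `paths`.
#' @export
simulate_dataset <- function(config, dir = NULL) {
  genos <- simulate_population(config)
  reads <- simulate_reads(genos, config)
  G_true <- dosage_grm(genos)
  phen <- simulate_phenotypes(genos, G_true, config)
  out <- list(genos = genos, reads = reads, G_true = G_true,
              phenotypes = phen)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      vcf = file.path(dir, "reads.vcf"),
      phenotypes = file.path(dir, "phenotypes.tsv"),
      sample_map = file.path(dir, "sample_map.tsv")
    )
    write_sim_vcf(reads, paths$vcf)
    write.table(phen$data, paths$phenotypes, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(reads$sample_map, paths$sample_map, sep = "\t",
                quote = FALSE, row.names = FALSE)
    out$paths <- paths
  }
  out
}

#' Write simulated reads as a minimal VCF with per-sample AD
#'
#' Emits biallelic SNP records (`REF=A`, `ALT=C`) with a single `AD` FORMAT
#' field carrying "ref,alt" read counts per sample; zero total depth is
#' written as `0,0` and read back as missing.
#'
#' @param reads A [read_depths][simulate_reads()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sim_vcf <- function(reads, path) {
  stopifnot(inherits(reads, "read_depths"))
  samples <- rownames(reads$ra)
  markers <- colnames(reads$ra)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=gbsblup-simulator",
    "##contig=<ID=1>",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allelic depths (ref,alt)\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  ), con)
  body <- vapply(seq_along(markers), function(j) {
    ad <- paste(reads$ra[, j], reads$rb[, j], sep = ",")
    paste(c("1", j * 10L, markers[j], "A", "C", ".", ".", ".", "AD", ad),
          collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}
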