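# read-depth and continuous-genotype containers -------------------------------

new_read_depths <- function(ra, rb, sample_map = NULL, tau_true = NULL,
                            skipped = tibble::tibble(reason = character(),
                                                     n = integer())) {
  storage.mode(ra) <- "integer"
  storage.mode(rb) <- "integer"
  if (!identical(dim(ra), dim(rb))) abort("`ra` and `rb` dimensions differ.")
  if (any(ra < 0) || any(rb < 0)) abort("read counts must be non-negative.")
  structure(
    list(ra = ra, rb = rb, sample_map = sample_map, tau_true = tau_true,
         skipped = skipped),
    class = "read_depths"
  )
}

#' @export
print.read_depths <- function(x, ...) {
  cat(sprintf("<read_depths> %d samples x %d markers\n",
              nrow(x$ra), ncol(x$ra)))
  if (nrow(x$skipped)) {
    cat("skipped records:\n")
    print(x$skipped)
  }
  invisible(x)
}

#' Read allelic depths from a VCF file
#'
#' Extracts per-sample reference/alternate read counts for biallelic SNP
#' records from a VCF (plain or gzipped). The per-sample `AD` field is used
#' when present, otherwise `RO`/`AO`. Multi-allelic records and records
#' without depth information are skipped with a logged count; sample and
#' marker order is preserved. Marker identity is `CHROM:POS:REF:ALT` unless
#' the record carries its own ID.
#'
#' @param path Path to a VCF file.
#' @return A `read_depths` object: integer matrices `ra` and `rb`
#'   (samples x markers) and a `skipped` tibble of per-reason record counts.
#' @examples
#' cfg <- sim_config(n_mothers = 5, n_markers = 8, n_families = 2, seed = 1)
#' reads <- simulate_reads(simulate_population(cfg), cfg)
#' vcf <- tempfile(fileext = ".vcf")
#' write_sim_vcf(reads, vcf)
#' rd <- read_vcf_depths(vcf)
#' dim(rd$ra)
#' @export
read_vcf_depths <- function(path) {
  if (!file.exists(path)) abort(sprintf("VCF file not found: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  samples <- colnames(v@gt)[-1]
  nrec <- nrow(fix) %||% 0L
  if (nrec == 0L || length(samples) == 0L) {
    empty <- matrix(integer(0), nrow = length(samples), ncol = 0,
                    dimnames = list(samples, character(0)))
    return(new_read_depths(empty, empty))
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)

  biallelic_snp <- !is.na(fix$ALT) & !grepl(",", fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L
  fmt <- v@gt[, "FORMAT"]
  has_ad <- vapply(strsplit(fmt, ":"), function(f) "AD" %in% f, logical(1))
  has_roao <- vapply(strsplit(fmt, ":"),
                     function(f) all(c("RO", "AO") %in% f), logical(1))
  usable <- biallelic_snp & (has_ad | has_roao)

  skipped <- tibble::tibble(
    reason = c("multiallelic_or_not_snp", "no_depth_field"),
    n = c(sum(!biallelic_snp),
          sum(biallelic_snp & !(has_ad | has_roao)))
  )
  skipped <- skipped[skipped$n > 0, ]

  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = ":"),
                fix$ID)
  parse_pair <- function(x) {
    # "a,b" -> c(a, b); missing -> 0 reads
    out <- matrix(0L, length(x), 2)
    ok <- !is.na(x) & x != "." & x != "./."
    if (any(ok)) {
      sp <- strsplit(x[ok], ",", fixed = TRUE)
      out[ok, 1] <- suppressWarnings(as.integer(vapply(sp, `[`, "", 1)))
      out[ok, 2] <- suppressWarnings(as.integer(vapply(sp, `[`, "", 2)))
    }
    out[is.na(out)] <- 0L
    out
  }
  ns <- length(samples)
  keep <- which(usable)
  ra <- matrix(0L, ns, length(keep), dimnames = list(samples, ids[keep]))
  rb <- ra
  for (jj in seq_along(keep)) {
    i <- keep[jj]
    if (has_ad[i]) {
      vals <- vcfR::extract.gt(v[i, ], element = "AD")[1, ]
      pair <- parse_pair(vals)
    } else {
      ro <- vcfR::extract.gt(v[i, ], element = "RO")[1, ]
      ao <- vcfR::extract.gt(v[i, ], element = "AO")[1, ]
      pair <- cbind(suppressWarnings(as.integer(ro)),
                    suppressWarnings(as.integer(ao)))
      pair[is.na(pair)] <- 0L
    }
    ra[, jj] <- pair[, 1]
    rb[, jj] <- pair[, 2]
  }
  if (nrow(skipped)) {
    inform(sprintf("skipped %d VCF record(s): %s",
                   sum(skipped$n),
                   paste(sprintf("%s (%d)", skipped$reason, skipped$n),
                         collapse = ", ")))
  }
  new_read_depths(ra, rb, skipped = skipped)
}

# continuous genotypes ---------------------------------------------------------

new_cont_geno <- function(f, ra, rt, filter_log = NULL, merged = FALSE,
                          imputed = FALSE) {
  structure(
    list(f = f, ra = ra, rt = rt,
         filter_log = filter_log %||%
           tibble::tibble(step = character(), markers = integer()),
         merged = merged, imputed = imputed),
    class = "cont_geno"
  )
}

#' @export
print.cont_geno <- function(x, ...) {
  cat(sprintf("<cont_geno> %d individuals x %d markers (%s%s)\n",
              nrow(x$f), ncol(x$f),
              if (x$merged) "merged" else "per-sample",
              if (x$imputed) ", imputed" else ""))
  if (nrow(x$filter_log)) print(x$filter_log)
  invisible(x)
}

#' Continuous genotypes from read depths
#'
#' Converts read counts to per-individual reference-allele frequencies
#' `f = R_A / (R_A + R_B)`; a cell with zero total reads is missing.
#'
#' @param rd A `read_depths` object from [read_vcf_depths()] or
#'   [simulate_reads()].
#' @return A `cont_geno` object carrying the frequency matrix `f` (with
#'   `NA` where no reads were observed) together with the supporting read
#'   counts used later for depth filtering and overdispersion estimation.
#' @seealso [marker_stats()] for per-marker mean frequency, call rate and
#'   mean depth.
#' @export
continuous_genotypes <- function(rd) {
  stopifnot(inherits(rd, "read_depths"))
  rt <- rd$ra + rd$rb
  f <- ifelse(rt > 0, rd$ra / rt, NA_real_)
  dimnames(f) <- dimnames(rd$ra)
  new_cont_geno(f, ra = rd$ra, rt = rt)
}

#' Per-marker summary statistics
#'
#' @param cg A `cont_geno` object.
#' @return A tibble with one row per marker: `marker`, `fbar` (mean observed
#'   frequency), `call_rate` (fraction of individuals with at least one
#'   read), and `mean_depth` (mean total reads over individuals with reads;
#'   `NaN` when no individual has reads).
#' @export
marker_stats <- function(cg) {
  stopifnot(inherits(cg, "cont_geno"))
  obs <- !is.na(cg$f)
  n_obs <- colSums(obs)
  tibble::tibble(
    marker = colnames(cg$f),
    fbar = colSums(cg$f * obs, na.rm = TRUE) / n_obs,
    call_rate = n_obs / nrow(cg$f),
    mean_depth = ifelse(n_obs > 0, colSums(cg$rt) / n_obs, NaN)
  )
}

#' Merge repeated samples into one row per individual
#'
#' When an individual was genotyped several times, its allele frequencies
#' are averaged into one frequency per marker over the replicates with
#' reads; the merged value is missing only if every replicate was missing.
#' Supporting read counts are summed across replicates, so downstream depth
#' statistics and overdispersion likelihoods use all reads of an individual.
#'
#' @param cg A `cont_geno` object whose rows are sequencing samples.
#' @param sample_map Data frame with columns `sample` and `individual`
#'   covering every row of `cg`.
#' @return A `cont_geno` object with one row per individual, ordered by
#'   first appearance in `sample_map`.
#' @export
merge_repeated_samples <- function(cg, sample_map) {
  stopifnot(inherits(cg, "cont_geno"))
  sample_map <- tibble::as_tibble(sample_map)
  if (!all(c("sample", "individual") %in% names(sample_map))) {
    abort("`sample_map` needs columns `sample` and `individual`.")
  }
  samples <- rownames(cg$f)
  unmapped <- setdiff(samples, sample_map$sample)
  if (length(unmapped)) {
    abort(sprintf("unmapped sample ID(s): %s",
                  paste(unmapped, collapse = ", ")))
  }
  ind <- sample_map$individual[match(samples, sample_map$sample)]
  individuals <- unique(sample_map$individual[sample_map$sample %in% samples])
  g <- match(ind, individuals)
  obs <- !is.na(cg$f)
  agg <- function(m) rowsum(m, g, reorder = TRUE)
  n_obs <- agg(obs + 0)
  fsum <- agg(ifelse(obs, cg$f, 0))
  f <- ifelse(n_obs > 0, fsum / n_obs, NA_real_)
  ra <- agg(cg$ra)
  rt <- agg(cg$rt)
  dimnames(f) <- dimnames(ra) <- dimnames(rt) <-
    list(individuals, colnames(cg$f))
  new_cont_geno(f, ra = ra, rt = rt, filter_log = cg$filter_log,
                merged = TRUE)
}

#' Filter markers on MAF, mean read depth, and call rate
#'
#' A marker survives iff `min(fbar, 1 - fbar) >= maf_min`, its mean total
#' read depth (over individuals with reads) lies in
#' `[depth_min, depth_max]`, and its call rate is at least
#' `call_rate_min`. The criteria are conjunctive, so the surviving set does
#' not depend on their order; the filter log nonetheless records sequential
#' attrition (MAF, then depth, then call rate) for reporting.
#'
#' @param cg A `cont_geno` object (typically after
#'   [merge_repeated_samples()], before imputation).
#' @param maf_min Minimum minor allele frequency, in `[0, 0.5]`.
#' @param depth_min,depth_max Bounds on the per-marker mean total read
#'   depth.
#' @param call_rate_min Minimum call rate, in `(0, 1]`.
#' @return The filtered `cont_geno` with an updated `filter_log`.
#' @export
filter_markers <- function(cg, maf_min = 0.05, depth_min = 10,
                           depth_max = 200, call_rate_min = 0.7) {
  stopifnot(inherits(cg, "cont_geno"))
  if (maf_min < 0 || maf_min > 0.5) abort("`maf_min` must lie in [0, 0.5].")
  if (depth_min > depth_max) abort("`depth_min` must not exceed `depth_max`.")
  if (call_rate_min <= 0 || call_rate_min > 1) {
    abort("`call_rate_min` must lie in (0, 1].")
  }
  st <- marker_stats(cg)
  maf_ok <- !is.na(st$fbar) & pmin(st$fbar, 1 - st$fbar) >= maf_min
  depth_ok <- !is.nan(st$mean_depth) &
    st$mean_depth >= depth_min & st$mean_depth <= depth_max
  cr_ok <- st$call_rate >= call_rate_min
  log <- tibble::tibble(
    step = c("input", sprintf("maf>=%g", maf_min),
             sprintf("mean_depth in [%g,%g]", depth_min, depth_max),
             sprintf("call_rate>=%g", call_rate_min)),
    markers = c(nrow(st), sum(maf_ok), sum(maf_ok & depth_ok),
                sum(maf_ok & depth_ok & cr_ok))
  )
  keep <- maf_ok & depth_ok & cr_ok
  if (!any(keep)) {
    abort(paste0(
      "all markers removed by filtering; attrition:\n",
      paste(sprintf("  %s: %d", log$step, log$markers), collapse = "\n")
    ))
  }
  new_cont_geno(cg$f[, keep, drop = FALSE],
                ra = cg$ra[, keep, drop = FALSE],
                rt = cg$rt[, keep, drop = FALSE],
                filter_log = dplyr::bind_rows(cg$filter_log, log),
                merged = cg$merged)
}

#' Impute missing genotypes with the marker mean
#'
#' Replaces each missing entry by the marker's mean observed frequency;
#' observed entries are untouched, so per-marker means are preserved
#' exactly.
#'
#' @param cg A `cont_geno` object in which every marker has at least one
#'   observed value (guaranteed after call-rate filtering).
#' @return A complete `cont_geno` (no missing values), flagged `imputed`.
#' @export
impute_missing <- function(cg) {
  stopifnot(inherits(cg, "cont_geno"))
  obs <- !is.na(cg$f)
  n_obs <- colSums(obs)
  if (any(n_obs == 0)) {
    abort(sprintf("marker(s) with no observed genotype: %s",
                  paste(colnames(cg$f)[n_obs == 0], collapse = ", ")))
  }
  fbar <- colSums(cg$f * obs, na.rm = TRUE) / n_obs
  f <- cg$f
  idx <- which(!obs, arr.ind = TRUE)
  if (nrow(idx)) f[idx] <- fbar[idx[, 2]]
  new_cont_geno(f, ra = cg$ra, rt = cg$rt, filter_log = cg$filter_log,
                merged = cg$merged, imputed = TRUE)
}
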