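# validation splits ------------------------------------------------------------

new_split <- function(strategy, label, est_records, val_records,
                      val_mothers, meta = list()) {
  structure(
    list(strategy = strategy, label = label, est_records = est_records,
         val_records = val_records, val_mothers = val_mothers, meta = meta),
    class = "validation_split"
  )
}

#' @export
print.validation_split <- function(x, ...) {
  cat(sprintf("<validation_split> %s '%s': %d estimation / %d validation records, %d validation mothers\n",
              x$strategy, x$label, length(x$est_records),
              length(x$val_records), length(x$val_mothers)))
  invisible(x)
}

#' Half-sib family cross-validation splits
#'
#' One split per family meeting the size floor: that family's mothers (and
#' all their progeny records) form the validation set and every other
#' record the estimation set. The genomic data of all mothers remains
#' available to the evaluator; only phenotypes are masked.
#'
#' @param data A [trait_data()] table.
#' @param families Data frame with columns `mother` and `family` covering
#'   every mother with records.
#' @param min_family_size Minimum number of mothers a family needs to
#'   become a validation fold.
#' @return A list of `validation_split` objects, ordered by family label.
#' @export
family_cv_splits <- function(data, families, min_family_size = 50) {
  families <- tibble::as_tibble(families)
  if (!all(c("mother", "family") %in% names(families))) {
    abort("`families` needs columns `mother` and `family`.")
  }
  uncovered <- setdiff(unique(data$mother_id), families$mother)
  if (length(uncovered)) {
    abort(sprintf("mother(s) without family label: %s",
                  paste(head(uncovered, 5), collapse = ", ")))
  }
  sizes <- dplyr::count(families, .data$family, name = "mothers")
  eligible <- sizes$family[sizes$mothers >= min_family_size]
  if (!length(eligible)) {
    abort(paste0(
      "no family reaches the size floor; family sizes:\n",
      paste(sprintf("  %s: %d", sizes$family, sizes$mothers),
            collapse = "\n")
    ))
  }
  purrr::map(sort(eligible), function(fam) {
    fam_mothers <- families$mother[families$family == fam]
    val <- data$record_id[data$mother_id %in% fam_mothers]
    new_split("family_cv", fam,
              est_records = setdiff(data$record_id, val),
              val_records = val,
              val_mothers = intersect(fam_mothers, unique(data$mother_id)),
              meta = list(family = fam, n_mothers = length(fam_mothers)))
  })
}

#' Forward-prediction split at a cutoff year
#'
#' Records from `cutoff_year` onward form the validation set. The split
#' also reports the mothers whose records all fall in the validation
#' period (those receive GEBV purely through genomic relationships).
#'
#' @param data A [trait_data()] table.
#' @param cutoff_year First year of the validation period (within the
#'   observed year range).
#' @return A `validation_split` with `meta$cutoff_year` and
#'   `meta$n_new_mothers`.
#' @export
forward_split <- function(data, cutoff_year) {
  yrs <- range(data$year)
  if (cutoff_year <= yrs[1] || cutoff_year > yrs[2]) {
    abort(sprintf("`cutoff_year` must lie in (%d, %d].", yrs[1], yrs[2]))
  }
  val <- data$record_id[data$year >= cutoff_year]
  est <- setdiff(data$record_id, val)
  if (!length(val) || !length(est)) {
    abort("cutoff leaves an empty estimation or validation set.")
  }
  est_mothers <- unique(data$mother_id[data$record_id %in% est])
  val_mothers <- unique(data$mother_id[data$record_id %in% val])
  new_split("forward", as.character(cutoff_year),
            est_records = est, val_records = val, val_mothers = val_mothers,
            meta = list(cutoff_year = cutoff_year,
                        n_new_mothers = length(setdiff(val_mothers,
                                                       est_mothers))))
}

# accuracy statistics -----------------------------------------------------------

#' Progeny means adjusted for fixed and permanent-environment effects
#'
#' For every validation record and trait, subtracts the fitted
#' trial-by-year effect and the fitted permanent-environment effect from
#' the phenotype and averages the residual within mother. Records whose
#' trial-by-year level was not estimable in the fit are dropped with a
#' warning; a permanent-environment level absent from the fit contributes
#' its BLUP of zero.
#'
#' @param data A [trait_data()] table restricted to the records to adjust
#'   (typically a validation set).
#' @param fit A `gblup_fit` providing the effect estimates.
#' @param traits Traits to adjust; defaults to the fit's traits.
#' @return A tibble: `mother`, `trait`, `adj_mean`, `n_records`.
#' @export
adjusted_progeny_means <- function(data, fit, traits = NULL) {
  stopifnot(inherits(fit, "gblup_fit"))
  traits <- traits %||% fit$traits
  data <- trait_data(data, traits)
  purrr::map_dfr(traits, function(tr) {
    fx <- fit$fixef[fit$fixef$trait == tr, ]
    pe <- fit$pe[fit$pe$trait == tr, ]
    d <- data[!is.na(data[[tr]]), ]
    fidx <- match(d$trial_year, fx$trial_year)
    dropped <- sum(is.na(fidx))
    if (dropped) {
      warn(sprintf(
        "%d record(s) dropped for trait %s: trial-by-year level not in fit",
        dropped, tr))
      d <- d[!is.na(fidx), ]
      fidx <- fidx[!is.na(fidx)]
    }
    pidx <- match(d$progeny_trial, pe$progeny_trial)
    adj <- d[[tr]] - fx$estimate[fidx] -
      ifelse(is.na(pidx), 0, pe$estimate[pidx])
    tibble::tibble(mother = d$mother_id, trait = tr, adj = adj) |>
      dplyr::summarise(adj_mean = mean(.data$adj),
                       n_records = dplyr::n(),
                       .by = c("mother", "trait"))
  })
}

#' Predictive ability
#'
#' Product-moment correlation between GEBV and adjusted mean progeny
#' performance over validation mothers.
#'
#' @param gebv Numeric vector of GEBV (one per validation mother).
#' @param adjusted_means Matching vector of adjusted progeny means.
#' @return The correlation, or `NA` (with a warning naming the cause) when
#'   fewer than 3 pairs are available or either vector has zero variance.
#' @export
predictive_ability <- function(gebv, adjusted_means) {
  ok <- stats::complete.cases(gebv, adjusted_means)
  if (sum(ok) < 3) {
    warn("fewer than 3 mothers with both GEBV and adjusted means.")
    return(NA_real_)
  }
  if (sd(gebv[ok]) == 0 || sd(adjusted_means[ok]) == 0) {
    warn("zero variance in GEBV or adjusted means; correlation undefined.")
    return(NA_real_)
  }
  cor(gebv[ok], adjusted_means[ok])
}

#' Legarra-Reverter statistics
#'
#' Compares GEBV from a full evaluation (all records) against a reduced
#' evaluation (validation phenotypes removed) over the validation mothers:
#' their correlation, and the slope and coefficient of determination of
#' the ordinary least-squares regression of full on reduced GEBV. A slope
#' below 1 indicates over-prediction (over-dispersion of the reduced GEBV),
#' above 1 under-prediction.
#'
#' @param gebv_full,gebv_reduced Numeric GEBV vectors aligned on the same
#'   validation mothers.
#' @return A one-row tibble: `correlation`, `slope`, `r2`, `n`.
#' @export
lr_statistics <- function(gebv_full, gebv_reduced) {
  ok <- stats::complete.cases(gebv_full, gebv_reduced)
  gf <- gebv_full[ok]; gr <- gebv_reduced[ok]
  if (length(gf) < 3 || sd(gr) == 0) {
    if (length(gf) >= 3) {
      warn("zero variance in reduced GEBV; slope undefined.")
    }
    return(tibble::tibble(correlation = NA_real_, slope = NA_real_,
                          r2 = NA_real_, n = length(gf)))
  }
  fit <- lm(gf ~ gr)
  r <- cor(gf, gr)
  tibble::tibble(
    correlation = r,
    slope = coef(fit)[[2]],
    r2 = r^2,
    n = length(gf)
  )
}

# orchestration -----------------------------------------------------------------

#' Run a validation study
#'
#' Fits the full evaluation once, then for every split refits the model on
#' the estimation records only (all mothers stay genotyped) and computes,
#' per trait: predictive ability (correlation of reduced-fit GEBV with
#' adjusted progeny means of the validation records) and the
#' Legarra-Reverter correlation, slope, and R-squared of full versus
#' reduced GEBV over the validation mothers.
#'
#' @param data A [trait_data()] table.
#' @param grm Relationship matrix for all mothers.
#' @param vc [variance_components()] used for both fits.
#' @param splits A list of `validation_split` objects (or a single one),
#'   from [family_cv_splits()] and/or [forward_split()].
#' @param traits Traits to evaluate; defaults to the traits of `vc`.
#' @param mode `"single"` or `"multi"` trait model.
#' @param adjust_with `"full"` (default) or `"reduced"`: which fit supplies
#'   the fixed/permanent-environment estimates when adjusting validation
#'   phenotypes.
#' @return A `validation_report` tibble: one row per strategy x split x
#'   trait with `n_val_mothers`, `predictive_ability`, `lr_correlation`,
#'   `lr_slope`, `lr_r2`.
#' @export
run_validation <- function(data, grm, vc, splits, traits = NULL,
                           mode = c("single", "multi"),
                           adjust_with = c("full", "reduced")) {
  mode <- match.arg(mode)
  adjust_with <- match.arg(adjust_with)
  traits <- traits %||% vc$traits
  if (inherits(splits, "validation_split")) splits <- list(splits)
  data <- trait_data(data, traits)
  fit_full <- solve_gblup(data, grm, vc, traits = traits, mode = mode)
  out <- purrr::map_dfr(splits, function(sp) {
    est <- data[data$record_id %in% sp$est_records, ]
    fit_red <- solve_gblup(est, grm, vc, traits = traits, mode = mode)
    val_data <- data[data$record_id %in% sp$val_records, ]
    adj <- adjusted_progeny_means(
      val_data, if (adjust_with == "full") fit_full else fit_red, traits
    )
    purrr::map_dfr(traits, function(tr) {
      gf <- fit_full$gebv[fit_full$gebv$trait == tr, ]
      gr <- fit_red$gebv[fit_red$gebv$trait == tr, ]
      vm <- sp$val_mothers
      gfv <- gf$gebv[match(vm, gf$mother)]
      grv <- gr$gebv[match(vm, gr$mother)]
      am <- adj[adj$trait == tr, ]
      pa <- predictive_ability(grv, am$adj_mean[match(vm, am$mother)])
      lr <- lr_statistics(gfv, grv)
      tibble::tibble(
        strategy = sp$strategy, split = sp$label, trait = tr,
        model = mode, n_val_mothers = length(vm),
        predictive_ability = pa,
        lr_correlation = lr$correlation, lr_slope = lr$slope,
        lr_r2 = lr$r2
      )
    })
  })
  class(out) <- c("validation_report", class(out))
  out
}
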