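# broom-style tidiers ----------------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a GBLUP fit into its GEBV table
#'
#' @param x A `gblup_fit`.
#' @param ... Unused.
#' @return A tibble with columns `mother`, `trait`, `gebv`.
#' @method tidy gblup_fit
#' @export
tidy.gblup_fit <- function(x, ...) x$gebv

#' One-row summary of a GBLUP fit
#'
#' @param x A `gblup_fit`.
#' @param ... Unused.
#' @method glance gblup_fit
#' @export
glance.gblup_fit <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    n_traits = length(x$traits),
    n_mothers = length(x$mothers),
    n_fixed_levels = nrow(x$fixef),
    n_pe_levels = length(unique(x$pe$progeny_trial))
  )
}

#' Tidy REML estimates into a long component table
#'
#' @param x A `reml_fit`.
#' @param ... Unused.
#' @return A tibble with columns `component` (`V_M`, `V_C`, `V_E`),
#'   `trait_row`, `trait_col`, `estimate`, and `std_error` (always `NA`:
#'   standard errors are not computed).
#' @method tidy reml_fit
#' @export
tidy.reml_fit <- function(x, ...) {
  purrr::map_dfr(c("V_M", "V_C", "V_E"), function(nm) {
    m <- x$vc[[nm]]
    idx <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE)
    tibble::tibble(
      component = nm,
      trait_row = x$traits[idx[, 1]],
      trait_col = x$traits[idx[, 2]],
      estimate = m[idx],
      std_error = NA_real_
    )
  })
}

#' One-row summary of a REML fit
#'
#' @param x A `reml_fit`.
#' @param ... Unused.
#' @method glance reml_fit
#' @export
glance.reml_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    n_iter = x$n_iter,
    converged = x$converged,
    n_traits = length(x$traits)
  )
}

#' Tidy a relationship matrix into its per-marker table
#'
#' For Beta-Binomial scaled matrices returns the per-marker tau/omega
#' table; otherwise the per-marker mean depths.
#'
#' @param x A `grm`.
#' @param ... Unused.
#' @method tidy grm
#' @export
tidy.grm <- function(x, ...) {
  if (!is.null(x$tau)) return(x$tau)
  tibble::tibble(marker = names(x$marker_mean_depth) %||%
                   seq_along(x$marker_mean_depth),
                 mean_depth = as.numeric(x$marker_mean_depth))
}

#' One-row summary of a relationship matrix
#'
#' @param x A `grm`.
#' @param ... Unused.
#' @method glance grm
#' @export
glance.grm <- function(x, ...) grm_summary(x)

#' Tidy genetic parameters
#'
#' @param x A `genetic_params` object.
#' @param ... Unused.
#' @method tidy genetic_params
#' @export
tidy.genetic_params <- function(x, ...) x$params
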