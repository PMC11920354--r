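# trait data ------------------------------------------------------------------

#' Validate a phenotype-record table
#'
#' Checks the columns the mixed model needs, coerces to a tibble, and
#' derives the two factors of the model: `trial_year` (trial-by-year
#' contemporary group, fitted fixed) and `progeny_trial`
#' (progeny-within-trial permanent-environment level).
#'
#' @param data Data frame with columns `record_id`, `mother_id`,
#'   `progeny_id`, `trial`, `year`, plus one numeric column per trait
#'   (missing trait values allowed).
#' @param traits Character vector of trait column names.
#' @return A tibble with the derived factor columns appended and the trait
#'   names stored in the `"traits"` attribute.
#' @export
trait_data <- function(data, traits) {
  data <- tibble::as_tibble(data)
  need <- c("record_id", "mother_id", "progeny_id", "trial", "year")
  missing_cols <- setdiff(c(need, traits), names(data))
  if (length(missing_cols)) {
    abort(sprintf("missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  data$trial_year <- paste(data$trial, data$year, sep = ":")
  data$progeny_trial <- paste(data$progeny_id, data$trial, sep = ":")
  attr(data, "traits") <- traits
  data
}

#' Variance-component container
#'
#' @param V_M,V_C,V_E Trait x trait mother, permanent-environment, and
#'   residual covariance matrices (symmetric PSD, equal dimensions).
#' @param traits Trait labels (defaults to the dimnames of `V_M` or
#'   `"t1"`, ...).
#' @return An object of class `variance_components`.
#' @export
variance_components <- function(V_M, V_C, V_E, traits = NULL) {
  V_M <- as.matrix(V_M); V_C <- as.matrix(V_C); V_E <- as.matrix(V_E)
  assert_psd(V_M, "V_M"); assert_psd(V_C, "V_C"); assert_psd(V_E, "V_E")
  if (nrow(V_M) != nrow(V_C) || nrow(V_M) != nrow(V_E)) {
    abort("`V_M`, `V_C`, `V_E` must have identical dimensions.")
  }
  traits <- traits %||% rownames(V_M) %||% paste0("t", seq_len(nrow(V_M)))
  dimnames(V_M) <- dimnames(V_C) <- dimnames(V_E) <- list(traits, traits)
  structure(list(V_M = V_M, V_C = V_C, V_E = V_E, traits = traits),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("<variance_components> %d trait(s): %s\n",
              length(x$traits), paste(x$traits, collapse = ", ")))
  for (nm in c("V_M", "V_C", "V_E")) {
    cat(nm, ":\n", sep = "")
    print(x[[nm]])
  }
  invisible(x)
}

vc_subset <- function(vc, traits) {
  variance_components(vc$V_M[traits, traits, drop = FALSE],
                      vc$V_C[traits, traits, drop = FALSE],
                      vc$V_E[traits, traits, drop = FALSE],
                      traits = traits)
}

# design and MME assembly ------------------------------------------------------

# Stacks observed trait-records trait-major and builds sparse X, Zm, Zc.
# Mothers come from the GRM row names so record-free genotyped mothers get
# columns (and hence predictions through G).
build_design <- function(data, traits, mothers) {
  if (is.null(mothers)) {
    abort("the relationship matrix must carry mother IDs as row names.")
  }
  if (is.null(attr(data, "traits"))) data <- trait_data(data, traits)
  unknown <- setdiff(unique(data$mother_id), mothers)
  if (length(unknown)) {
    abort(sprintf("mother(s) with records but no genotype: %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  n <- length(mothers)
  obs <- purrr::map_dfr(seq_along(traits), function(t) {
    y <- data[[traits[t]]]
    keep <- which(!is.na(y))
    tibble::tibble(trait = t, row = keep, y = y[keep],
                   mother = data$mother_id[keep],
                   trial_year = data$trial_year[keep],
                   progeny_trial = data$progeny_trial[keep])
  })
  if (!nrow(obs)) abort("no observed trait records.")
  nt <- length(traits)
  N <- nrow(obs)

  fx_levels <- purrr::map(seq_len(nt), function(t) {
    sort(unique(obs$trial_year[obs$trait == t]))
  })
  fx_offset <- c(0, cumsum(lengths(fx_levels)))
  nf <- fx_offset[nt + 1]
  xj <- fx_offset[obs$trait] +
    purrr::map2_int(obs$trait, obs$trial_year,
                    function(t, l) match(l, fx_levels[[t]]))
  X <- Matrix::sparseMatrix(i = seq_len(N), j = xj, x = 1, dims = c(N, nf))

  mj <- (obs$trait - 1L) * n + match(obs$mother, mothers)
  Zm <- Matrix::sparseMatrix(i = seq_len(N), j = mj, x = 1,
                             dims = c(N, nt * n))

  pe_levels <- sort(unique(obs$progeny_trial))
  q <- length(pe_levels)
  cj <- (obs$trait - 1L) * q + match(obs$progeny_trial, pe_levels)
  Zc <- Matrix::sparseMatrix(i = seq_len(N), j = cj, x = 1,
                             dims = c(N, nt * q))

  list(obs = obs, X = X, Zm = Zm, Zc = Zc, W = cbind(X, Zm, Zc),
       y = obs$y, mothers = mothers, n = n, q = q, nt = nt,
       fx_levels = fx_levels, fx_offset = fx_offset, nf = nf,
       pe_levels = pe_levels, traits = traits,
       record_row = obs$row)
}

# Sparse inverse residual covariance over stacked observations: block per
# record, inv(V_E[obs, obs]) linking co-observed traits of the same record.
build_rinv <- function(des, V_E) {
  N <- nrow(des$obs)
  if (des$nt == 1L) {
    return(list(Rinv = Matrix::Diagonal(N, 1 / V_E[1, 1]),
                logdet = N * log(V_E[1, 1])))
  }
  key <- split(seq_len(N), des$obs$row)
  trs <- des$obs$trait
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  logdet <- 0
  pat_cache <- new.env(parent = emptyenv())
  for (rows in key) {
    o <- trs[rows]
    pk <- paste(o, collapse = ",")
    inv <- get0(pk, envir = pat_cache)
    if (is.null(inv)) {
      inv <- solve(V_E[o, o, drop = FALSE])
      attr(inv, "ld") <- determinant(V_E[o, o, drop = FALSE])$modulus[1]
      assign(pk, inv, envir = pat_cache)
    }
    logdet <- logdet + attr(inv, "ld")
    k <- length(rows)
    ii <- c(ii, rep(rows, each = k))
    jj <- c(jj, rep(rows, times = k))
    xx <- c(xx, as.vector(t(inv)))
  }
  list(Rinv = Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(N, N)),
       logdet = logdet)
}

inv_pd <- function(m, name) {
  out <- tryCatch(chol2inv(chol(m)), error = function(e) NULL)
  if (is.null(out)) {
    abort(sprintf("`%s` is singular; the model needs it positive definite.",
                  name))
  }
  out
}

# Coefficient matrix of the mixed-model equations and its pieces.
assemble_mme <- function(des, Ginv, vc) {
  VMi <- inv_pd(vc$V_M, "V_M")
  VCi <- inv_pd(vc$V_C, "V_C")
  r <- build_rinv(des, vc$V_E)
  W <- des$W
  WtRi <- Matrix::t(W) %*% r$Rinv
  penalty <- Matrix::bdiag(
    Matrix::Matrix(0, des$nf, des$nf),
    Matrix::Matrix(VMi %x% Ginv),
    Matrix::Matrix(VCi) %x% Matrix::Diagonal(des$q)
  )
  C <- WtRi %*% W + penalty
  idx_m <- des$nf + seq_len(des$nt * des$n)
  idx_c <- des$nf + des$nt * des$n + seq_len(des$nt * des$q)
  rhs <- as.numeric(WtRi %*% des$y)
  list(C = C, rhs = rhs, Rinv = r$Rinv, logdet_R = r$logdet,
       idx_f = seq_len(des$nf), idx_m = idx_m, idx_c = idx_c)
}

solve_theta <- function(mme) {
  as.numeric(Matrix::solve(mme$C, mme$rhs))
}

# G inverse with optional ridge when ill-conditioned
ginv_ridge <- function(G, ridge = 1e-6) {
  ch <- tryCatch(chol(G), error = function(e) NULL)
  if (is.null(ch)) {
    inform(sprintf("G is singular; adding ridge %g to its diagonal", ridge))
    ch <- chol(G + diag(ridge * mean(diag(G)) + ridge, nrow(G)))
  }
  list(Ginv = chol2inv(ch), logdet = 2 * sum(log(diag(ch))))
}

# GBLUP ------------------------------------------------------------------------

#' Solve single- or multi-trait GBLUP
#'
#' Solves the mixed-model equations for
#' `y = X b + Z_m m + Z_c c + e` with trial-by-year fixed effects (cell
#' means per trait), mother genetic effects `m ~ N(0, V_M (x) G)`,
#' progeny-within-trial permanent-environment effects
#' `c ~ N(0, V_C (x) I)`, and residuals `e ~ N(0, V_E)` block-wise over the
#' traits observed on each record. Genotyped mothers without records
#' receive GEBV through their genomic relationships with recorded mothers.
#'
#' In `mode = "single"` each trait is fitted separately using the relevant
#' diagonal elements of the covariance matrices.
#'
#' @param data A [trait_data()] table (or a data frame with the same
#'   columns).
#' @param grm A [genomic_relationship()] object or plain relationship
#'   matrix whose row names are the mother IDs.
#' @param vc A [variance_components()] object covering `traits`.
#' @param traits Traits to fit; defaults to all traits of `vc`.
#' @param mode `"multi"` (joint fit) or `"single"` (per-trait fits).
#' @param ridge Diagonal ridge added to a singular G before inversion.
#' @return An object of class `gblup_fit` with tibbles `gebv`
#'   (`mother`, `trait`, `gebv`), `fixef` (`trait`, `trial_year`,
#'   `estimate`), and `pe` (`trait`, `progeny_trial`, `estimate`), plus the
#'   variance components and model tag used.
#' @export
solve_gblup <- function(data, grm, vc, traits = NULL,
                        mode = c("multi", "single"), ridge = 1e-6) {
  mode <- match.arg(mode)
  G <- if (inherits(grm, "grm")) grm$G else as.matrix(grm)
  traits <- traits %||% vc$traits
  if (!all(traits %in% vc$traits)) {
    abort("`traits` must be covered by the variance components.")
  }
  if (mode == "single" && length(traits) > 1L) {
    fits <- purrr::map(traits, function(tr) {
      solve_gblup(data, grm, vc, traits = tr, mode = "single", ridge = ridge)
    })
    return(structure(
      list(gebv = purrr::map_dfr(fits, "gebv"),
           fixef = purrr::map_dfr(fits, "fixef"),
           pe = purrr::map_dfr(fits, "pe"),
           vc = vc, mode = "single", traits = traits,
           mothers = rownames(G)),
      class = "gblup_fit"
    ))
  }
  vcs <- vc_subset(vc, traits)
  data <- trait_data(data, traits)
  des <- build_design(data, traits, rownames(G))
  gi <- ginv_ridge(G, ridge)
  mme <- assemble_mme(des, gi$Ginv, vcs)
  theta <- solve_theta(mme)

  nt <- des$nt; n <- des$n; q <- des$q
  m_hat <- matrix(theta[mme$idx_m], n, nt,
                  dimnames = list(des$mothers, traits))
  c_hat <- matrix(theta[mme$idx_c], q, nt,
                  dimnames = list(des$pe_levels, traits))
  fixef <- purrr::map_dfr(seq_len(nt), function(t) {
    lv <- des$fx_levels[[t]]
    tibble::tibble(trait = traits[t], trial_year = lv,
                   estimate = theta[des$fx_offset[t] + seq_along(lv)])
  })
  gebv <- tibble::as_tibble(m_hat, rownames = "mother") |>
    tidyr::pivot_longer(-"mother", names_to = "trait", values_to = "gebv")
  pe <- tibble::as_tibble(c_hat, rownames = "progeny_trial") |>
    tidyr::pivot_longer(-"progeny_trial", names_to = "trait",
                        values_to = "estimate") |>
    dplyr::select("trait", "progeny_trial", "estimate")
  structure(
    list(gebv = gebv, fixef = fixef, pe = pe, vc = vc,
         mode = if (length(traits) == 1L && mode == "single") "single"
                else "multi",
         traits = traits, mothers = des$mothers),
    class = "gblup_fit"
  )
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf("<gblup_fit> %s-trait model: %s; %d mothers\n",
              if (x$mode == "single") "single" else "multiple",
              paste(x$traits, collapse = ", "), length(x$mothers)))
  print(head(x$gebv))
  invisible(x)
}

#' GEBV of a fit as a wide tibble
#'
#' @param fit A `gblup_fit`.
#' @return A tibble with one row per mother and one column per trait.
#' @export
gebv_matrix <- function(fit) {
  stopifnot(inherits(fit, "gblup_fit"))
  tidyr::pivot_wider(fit$gebv, names_from = "trait", values_from = "gebv")
}
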