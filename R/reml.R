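# deterministic EM-REML for the GBLUP model -----------------------------------

default_init <- function(data, traits) {
  vp <- vapply(traits, function(tr) var(data[[tr]], na.rm = TRUE), numeric(1))
  variance_components(diag(0.2 * vp, length(vp)),
                      diag(0.2 * vp, length(vp)),
                      diag(0.6 * vp, length(vp)),
                      traits = traits)
}

flatten_vc <- function(vc) {
  nt <- length(vc$traits)
  out <- c()
  for (nm in c("V_M", "V_C", "V_E")) {
    m <- vc[[nm]]
    for (s in seq_len(nt)) for (t in s:nt) {
      out[sprintf("%s.%d.%d", nm, s, t)] <- m[s, t]
    }
  }
  out
}

#' Estimate variance components by EM-REML
#'
#' Deterministic Expectation-Maximisation REML for the GBLUP model fitted
#' by [solve_gblup()]: mother effects with covariance `V_M (x) G`,
#' progeny-within-trial permanent-environment effects with covariance
#' `V_C (x) I`, per-record residual blocks from `V_E`. The E-step uses the
#' exact conditional expectations (trace terms from the inverted
#' mixed-model coefficient matrix), which is feasible at the problem sizes
#' this package targets; records with some traits unobserved contribute
#' through the usual missing-data conditional moments. The restricted
#' log-likelihood is non-decreasing across iterations.
#'
#' @param data A [trait_data()] table.
#' @param grm Relationship matrix (a `grm` object or plain matrix).
#' @param init Starting [variance_components()]; `NULL` starts from an
#'   equal split of the phenotypic variance (20/20/60).
#' @param traits Traits to include; defaults to the traits of `init`.
#' @param tol Convergence threshold on the maximum relative round-to-round
#'   change in any (co)variance component.
#' @param max_iter Iteration cap; hitting it returns `converged = FALSE`.
#' @param ridge Ridge added to a singular G before inversion.
#' @return An object of class `reml_fit`: the estimated
#'   [variance_components()] in `$vc`, the iteration `$trajectory` (a
#'   tibble with the restricted log-likelihood and every component per
#'   iteration), `$converged`, `$n_iter`, and the final `$loglik`.
#' @export
em_reml <- function(data, grm, init = NULL, traits = NULL, tol = 1e-8,
                    max_iter = 200, ridge = 1e-6) {
  G <- if (inherits(grm, "grm")) grm$G else as.matrix(grm)
  if (is.null(init)) {
    if (is.null(traits)) abort("supply `traits` when `init` is NULL.")
    init <- default_init(data, traits)
  }
  traits <- traits %||% init$traits
  vc <- vc_subset(init, traits)
  data <- trait_data(data, traits)
  des <- build_design(data, traits, rownames(G))
  n <- des$n; q <- des$q; nt <- des$nt; N <- nrow(des$obs)
  n_rec <- length(unique(des$obs$row))

  if (max(table(paste(des$obs$progeny_trial, des$obs$trait))) < 2) {
    warn(paste("every progeny-within-trial level is observed once per trait;",
               "V_C and V_E are confounded"))
  }

  gi <- ginv_ridge(G, ridge)
  Ginv <- gi$Ginv
  logdetG <- gi$logdet
  W <- des$W
  y <- des$y
  rec_rows <- split(seq_len(N), des$obs$row)
  rec_traits <- split(des$obs$trait, des$obs$row)

  # Single-trait fast path: R is diagonal and the permanent-environment
  # block of the coefficient matrix is diagonal, so it is absorbed exactly
  # into the fixed+mother equations; only a (nf + n)-dimensional system is
  # factorised per iteration and all trace terms are recovered from the
  # absorbed inverse.
  fast <- nt == 1L
  if (fast) {
    nx <- des$nf + n
    Wx <- W[, seq_len(nx), drop = FALSE]
    Wc <- W[, nx + seq_len(q), drop = FALSE]
    Axx <- as.matrix(Matrix::crossprod(Wx))
    Bxc <- Matrix::crossprod(Wx, Wc)
    b_sp <- as(Bxc, "TsparseMatrix")
    b_cells <- cbind(b_sp@i + 1L, b_sp@j + 1L)
    b_vals <- b_sp@x
    dcc <- Matrix::colSums(Wc)
    Wty_x <- as.numeric(Matrix::crossprod(Wx, y))
    Wty_c <- as.numeric(Matrix::crossprod(Wc, y))
    yty <- sum(y^2)
    mrows <- des$nf + seq_len(n)
  }

  traj <- vector("list", max_iter)
  converged <- FALSE
  loglik <- NA_real_
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (fast) {
      s_e <- vc$V_E[1, 1]; s_m <- vc$V_M[1, 1]; s_c <- vc$V_C[1, 1]
      d <- dcc / s_e + 1 / s_c
      A <- Axx / s_e
      A[mrows, mrows] <- A[mrows, mrows] + Ginv / s_m
      BDi <- b_sp
      BDi@x <- b_vals / s_e / d[b_cells[, 2]]
      S <- A - as.matrix(BDi %*% Matrix::t(b_sp)) / s_e
      chS <- chol(S)
      Sinv <- chol2inv(chS)
      rx <- Wty_x / s_e
      rc <- Wty_c / s_e
      thx <- as.numeric(Sinv %*% (rx - as.numeric(BDi %*% rc)))
      thc <- (rc - as.numeric(Matrix::crossprod(b_sp, thx)) / s_e) / d
      logdetC <- 2 * sum(log(diag(chS))) + sum(log(d))
      quad <- yty / s_e - (sum(thx * rx) + sum(thc * rc))
      loglik <- -0.5 * (N * log(s_e) + n * log(s_m) + logdetG +
                          q * log(s_c) + logdetC + quad)
      traj[[iter]] <- c(iter = iter, loglik = loglik, flatten_vc(vc))

      m_hat <- thx[mrows]
      VM_new <- matrix((sum(m_hat * (Ginv %*% m_hat)) +
                          sum(Ginv * Sinv[mrows, mrows])) / n)
      Tm <- Sinv %*% as.matrix(BDi)            # S^-1 B D^-1, (nf+n) x q
      bTb <- colSums(as.matrix(BDi) * Tm)      # diag of D^-1 B' S^-1 B D^-1
      diag_cc <- 1 / d + bTb
      VC_new <- matrix((sum(thc^2) + sum(diag_cc)) / q)
      # residual trace over the sparse pattern of W'W
      d_tot <- sum(Sinv * Axx) -
        2 * sum(b_vals * Tm[b_cells]) +
        sum(dcc * diag_cc)
      ehat <- y - as.numeric(Wx %*% thx) - as.numeric(Wc %*% thc)
      VE_new <- matrix((sum(ehat^2) + d_tot) / N)
    } else {
      mme <- assemble_mme(des, Ginv, vc)
      Cd <- as.matrix(mme$C)
      ch <- chol(Cd)
      Cinv <- chol2inv(ch)
      theta <- as.numeric(Cinv %*% mme$rhs)
      yRy <- as.numeric(y %*% (mme$Rinv %*% y))
      loglik <- -0.5 * (mme$logdet_R +
                          n * determinant(vc$V_M)$modulus[1] +
                          nt * logdetG +
                          q * determinant(vc$V_C)$modulus[1] +
                          2 * sum(log(diag(ch))) +
                          yRy - sum(theta * mme$rhs))
      traj[[iter]] <- c(iter = iter, loglik = loglik, flatten_vc(vc))

      # E-step / M-step updates
      m_hat <- matrix(theta[mme$idx_m], n, nt)
      c_hat <- matrix(theta[mme$idx_c], q, nt)
      VM_new <- matrix(0, nt, nt)
      VC_new <- matrix(0, nt, nt)
      for (s in seq_len(nt)) for (t in s:nt) {
        bs <- mme$idx_m[(s - 1) * n + seq_len(n)]
        bt <- mme$idx_m[(t - 1) * n + seq_len(n)]
        VM_new[s, t] <- VM_new[t, s] <-
          (sum(m_hat[, s] * (Ginv %*% m_hat[, t])) +
             sum(Ginv * Cinv[bs, bt])) / n
        cs <- mme$idx_c[(s - 1) * q + seq_len(q)]
        ct <- mme$idx_c[(t - 1) * q + seq_len(q)]
        VC_new[s, t] <- VC_new[t, s] <-
          (sum(c_hat[, s] * c_hat[, t]) +
             sum(diag(Cinv[cs, ct, drop = FALSE]))) / q
      }

      fitted <- as.numeric(W %*% theta)
      ehat <- y - fitted
      WC <- as.matrix(W %*% Cinv)
      S <- matrix(0, nt, nt)
      VE <- vc$V_E
      for (r in seq_along(rec_rows)) {
        rows <- rec_rows[[r]]
        o <- rec_traits[[r]]
        Wr <- W[rows, , drop = FALSE]
        Soo <- tcrossprod(ehat[rows]) +
          as.matrix(WC[rows, , drop = FALSE] %*% Matrix::t(Wr))
        if (length(o) == nt) {
          S[o, o] <- S[o, o] + Soo
        } else {
          mi <- setdiff(seq_len(nt), o)
          B <- VE[mi, o, drop = FALSE] %*% solve(VE[o, o, drop = FALSE])
          Smo <- B %*% Soo
          Smm <- Smo %*% t(B) +
            (VE[mi, mi, drop = FALSE] - B %*% VE[o, mi, drop = FALSE])
          S[o, o] <- S[o, o] + Soo
          S[mi, o] <- S[mi, o] + Smo
          S[o, mi] <- S[o, mi] + t(Smo)
          S[mi, mi] <- S[mi, mi] + Smm
        }
      }
      VE_new <- (S + t(S)) / 2 / n_rec
    }

    old <- flatten_vc(vc)
    vc <- variance_components(VM_new, VC_new, VE_new, traits = traits)
    new <- flatten_vc(vc)
    rel <- abs(new - old) / pmax(abs(old), 1e-12)
    if (max(rel) < tol) {
      converged <- TRUE
      break
    }
  }
  trajectory <- tibble::as_tibble(do.call(rbind, traj[seq_len(iter)]))
  structure(
    list(vc = vc, trajectory = trajectory, converged = converged,
         n_iter = iter, loglik = loglik, traits = traits),
    class = "reml_fit"
  )
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("<reml_fit> %d iteration(s), %sconverged, logLik %.4f\n",
              x$n_iter, if (x$converged) "" else "NOT ", x$loglik))
  print(x$vc)
  invisible(x)
}

#' Standard errors of REML estimates (not computed)
#'
#' Sampling-based standard errors for REML variance components are outside
#' this package's scope; reports carry `NA` in their place.
#'
#' @param ... Ignored.
#' @export
reml_standard_errors <- function(...) {
  abort("standard errors of REML estimates are not computed by gbsblup.",
        class = "gbsblup_not_implemented")
}
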