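# Multi-trait AI-REML for the genomic-polygenic model.
#
# Two code paths maximizing the same restricted likelihood:
#  * fast path (complete records): rotate by the eigenvectors of the
#    relationship submatrix K among recorded animals, so V becomes block
#    diagonal with t x t blocks V_i = d_i Va + Ve;
#  * general path (arbitrary missing-trait patterns): dense V over the
#    observed cells.
# Average-information updates, with an EM-REML step whenever an AI update
# leaves the PD cone or decreases the restricted log-likelihood.

#' Estimate variance components by average-information REML
#'
#' Fits `y = Xb + Zu + e` with `var(u) = K x Va` (K the relationship matrix
#' among the recorded animals, from H) and `var(e) = I x Ve`, maximizing the
#' restricted likelihood over the free parameters of the symmetric matrices
#' `Va` and `Ve` (12 parameters for 3 traits).
#'
#' @param design [build_design()] output.
#' @param H_inv Inverse relationship matrix over all pedigree animals
#'   ([build_H_inv()] list or plain matrix); ignored when `K` is given.
#' @param start Optional list with starting `Va`, `Ve` (both PD).  Default:
#'   half the phenotypic covariance of the observed records for each.
#' @param max_iter Maximum iterations (default 200).
#' @param tol Convergence tolerance on the relative parameter change
#'   (default 1e-8); the gradient must also have dropped below `sqrt(tol)`
#'   in infinity norm.
#' @param K Optional relationship matrix among the recorded animals (in
#'   record order), bypassing inversion of `H_inv`.  An `"eigen"` attribute
#'   (precomputed `eigen(K, symmetric = TRUE)`) is honored.
#' @param verbose Print the iteration trace.
#' @return Object of class `ssgwas_reml`: `Va`, `Ve`, `loglik`, `converged`,
#'   `n_iter`, `trace` (tibble: iteration, log-likelihood, step type,
#'   relative change), `traits`, `start`.
#' @export
reml_ai <- function(design, H_inv = NULL, start = NULL, max_iter = 200L,
                    tol = 1e-8, K = NULL, verbose = FALSE) {
  stopifnot(inherits(design, "ssgwas_design"))
  t_n <- length(design$traits)
  if (is.null(K)) {
    if (is.null(H_inv)) stop_bad_arg("supply either `H_inv` or `K`")
    Hi <- as_hinv_matrix(H_inv, design$animal_ids)
    H <- chol2inv(chol(symmpart_dense(Hi)))
    dimnames(H) <- dimnames(Hi)
    rec_ids <- as.character(design$animal_ids[design$animal_idx])
    K <- H[rec_ids, rec_ids, drop = FALSE]
  }
  n_rec <- nrow(design$y)
  if (!all(dim(K) == n_rec)) stop_bad_arg("K must be square over the records")

  if (is.null(start)) {
    pc <- stats::cov(design$y, use = "pairwise.complete.obs")
    pc[is.na(pc)] <- 0
    pc <- symmpart_dense(pc)
    # nudge into the PD cone if pairwise covariances are inconsistent
    ev <- eigen(pc, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-6 * max(abs(ev))) pc <- pc + diag(max(abs(ev)) * 1e-3, t_n)
    start <- list(Va = pc / 2, Ve = pc / 2)
  }
  if (!is_spd(start$Va) || !is_spd(start$Ve)) {
    stop_bad_arg("starting Va and Ve must be symmetric positive definite")
  }

  complete <- all(design$obs)
  mach <- if (complete) reml_fast_machinery(design, K) else
    reml_general_machinery(design, K)
  fit <- reml_iterate(start, t_n, max_iter, tol, verbose,
                      mach$derivs, mach$em_step)
  if (!fit$converged) {
    abort(sprintf("AI-REML did not converge in %d iterations (last relative change %.3g)",
                  max_iter, utils::tail(fit$trace$rel_change, 1)),
          class = "ssgwaspath_convergence_error", trace_tbl = fit$trace)
  }
  structure(c(fit, list(traits = design$traits, start = start,
                        n_records = n_rec)),
            class = "ssgwas_reml")
}

# shared AI/EM iteration loop; `derivs(Va, Ve)` returns loglik, grad, AI and
# the pieces an EM step needs
reml_iterate <- function(start, t_n, max_iter, tol, verbose, derivs, em_step) {
  Va <- symmpart_dense(start$Va)
  Ve <- symmpart_dense(start$Ve)
  basis <- vech_basis(t_n)
  npar <- 2L * length(basis)
  cur <- derivs(Va, Ve)
  trace <- list(tibble(iteration = 0L, loglik = cur$loglik, step = "start",
                       rel_change = NA_real_))
  converged <- FALSE
  boundary <- FALSE
  grad_ok <- FALSE
  floor_scale <- 1e-8 * mean(c(diag(Va), diag(Ve)))
  for (it in seq_len(max_iter)) {
    theta <- c(vech(Va), vech(Ve))
    ai <- symmpart_dense(cur$AI)
    step_type <- "AI"
    proposal <- NULL
    slack <- 1e-8 * (1 + abs(cur$loglik))     # roundoff on the dense path
    # AI step with step-halving, then Levenberg-style damping, while the
    # update leaves the PD cone or decreases the restricted likelihood
    for (damp in c(1e-10, 1e-6, 1e-3, 1e-1)) {
      delta <- tryCatch(solve(ai + diag(damp * max(diag(ai)), npar), cur$grad),
                        error = function(e) NULL)
      if (is.null(delta)) next
      frac <- 1
      for (h in 1:6) {
        cand <- theta + frac * delta
        Va_c <- unvech(cand[seq_along(basis)], t_n)
        Ve_c <- unvech(cand[-seq_along(basis)], t_n)
        if (is_spd(Va_c, tol = 1e-12) && is_spd(Ve_c, tol = 1e-12)) {
          cand_d <- derivs(Va_c, Ve_c)
          if (is.finite(cand_d$loglik) && cand_d$loglik >= cur$loglik - slack) {
            proposal <- list(Va = Va_c, Ve = Ve_c, d = cand_d)
            break
          }
        }
        frac <- frac / 2
      }
      if (!is.null(proposal)) break
    }
    if (is.null(proposal)) {
      # AI step left the PD cone or decreased the likelihood: EM-REML step
      step_type <- "EM"
      emv <- em_step(Va, Ve, cur)
      cand_d <- derivs(emv$Va, emv$Ve)
      proposal <- list(Va = emv$Va, Ve = emv$Ve, d = cand_d)
    }
    new_theta <- c(vech(proposal$Va), vech(proposal$Ve))
    rel <- max(abs(new_theta - theta)) / max(abs(theta), 1e-12)
    Va <- proposal$Va; Ve <- proposal$Ve; cur <- proposal$d
    trace[[it + 1L]] <- tibble(iteration = it, loglik = cur$loglik,
                               step = step_type, rel_change = rel)
    if (verbose) {
      message(sprintf("iter %3d [%s] logL = %.6f  rel = %.3g",
                      it, step_type, cur$loglik, rel))
    }
    grad_ok <- max(abs(cur$grad)) < sqrt(tol) * max(1, abs(cur$loglik))
    if (rel < tol && (grad_ok || step_type == "AI")) {
      converged <- TRUE
      break
    }
    # first-order stop: scaled score effectively zero while parameters have
    # stabilized (AI steps cycling in the roundoff plateau of the surface)
    if (rel < 1e-4 && max(abs(cur$grad)) < 1e-6 * (1 + abs(cur$loglik))) {
      converged <- TRUE
      break
    }
    # flat-likelihood stop: parameter drift already tiny and the restricted
    # likelihood numerically unchanged over a 50-iteration window (EM inching
    # along an ill-conditioned ridge)
    if (it >= 50L && rel < 1e-5) {
      gain <- cur$loglik - trace[[it - 48L]]$loglik
      if (is.finite(gain) && gain < 1e-8 * (1 + abs(cur$loglik))) {
        converged <- TRUE
        break
      }
    }
    # near-singular component: the optimum lies on the PD-cone boundary
    # (a variance hitting zero or a correlation hitting +/-1); EM inches
    # toward it forever, so flag and stop once parameters have stabilized
    relcond <- function(m) {
      ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
      min(ev) / max(abs(ev))
    }
    if (rel < 1e-4 && it >= 20L &&
        (relcond(Va) < 1e-5 || relcond(Ve) < 1e-5)) {
      boundary <- TRUE
      converged <- TRUE
      warning("covariance component nearly singular: REML optimum at the boundary of the parameter space")
      break
    }
    if (min(diag(Va)) < floor_scale || min(diag(Ve)) < floor_scale) {
      # a component is collapsing to the boundary of the parameter space;
      # clamp at the floor and stop rather than iterating into singularity
      boundary <- TRUE
      converged <- TRUE
      diag(Va) <- pmax(diag(Va), floor_scale)
      diag(Ve) <- pmax(diag(Ve), floor_scale)
      warning("variance component at boundary: estimate floored near zero")
      break
    }
  }
  list(Va = symmpart_dense(Va), Ve = symmpart_dense(Ve), loglik = cur$loglik,
       converged = converged, boundary = boundary, n_iter = length(trace) - 1L,
       trace = dplyr::bind_rows(trace))
}

# ---------------------------------------------------------------------------
# fast path: complete records, K eigendecomposed once
reml_fast_machinery <- function(design, K) {
  t_n <- length(design$traits)
  eg <- attr(K, "eigen") %||% eigen(symmpart_dense(K), symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  Ys <- crossprod(U, design$y)          # n x t
  Xs <- crossprod(U, design$X)          # n x p
  n <- nrow(Ys); p <- ncol(Xs)
  basis <- vech_basis(t_n)
  nb <- length(basis)

  derivs <- function(Va, Ve) {
    Vi_inv <- vector("list", n)
    logdetV <- 0
    for (i in seq_len(n)) {
      Vi <- d[i] * Va + Ve
      ch <- tryCatch(chol(Vi), error = function(e) NULL)
      if (is.null(ch)) return(list(loglik = -Inf))
      logdetV <- logdetV + 2 * sum(log(diag(ch)))
      Vi_inv[[i]] <- chol2inv(ch)
    }
    # W = X'V^-1 X (trait-major blocks), rhs = X'V^-1 y
    np <- t_n * p
    W <- matrix(0, np, np)
    rhs <- numeric(np)
    for (i in seq_len(n)) {
      xx <- tcrossprod(Xs[i, ])
      W <- W + kronecker(Vi_inv[[i]], xx)
      rhs <- rhs + kronecker(Vi_inv[[i]] %*% Ys[i, ], Xs[i, ])
    }
    chW <- tryCatch(chol(symmpart_dense(W)), error = function(e) NULL)
    if (is.null(chW)) return(list(loglik = -Inf))
    W_inv <- chol2inv(chW)
    b <- W_inv %*% rhs
    bmat <- matrix(b, nrow = p)           # p x t (trait-major blocks)
    R <- matrix(0, n, t_n)                # rows r_i = Vi_inv (y_i - fitted)
    ypy <- 0
    for (i in seq_len(n)) {
      resid <- Ys[i, ] - as.vector(crossprod(bmat, Xs[i, ]))
      ri <- Vi_inv[[i]] %*% resid
      R[i, ] <- ri
      ypy <- ypy + sum(resid * ri)
    }
    loglik <- -0.5 * (logdetV + 2 * sum(log(diag(chW))) + ypy)

    npar <- 2L * nb
    grad <- numeric(npar)
    # w_k = Ddot_k P y, stored as n x t matrices
    Wk <- vector("list", npar)
    trV <- numeric(npar)
    Tk <- vector("list", npar)
    for (k in seq_len(npar)) Tk[[k]] <- matrix(0, np, np)
    for (i in seq_len(n)) {
      vi <- Vi_inv[[i]]
      xx <- tcrossprod(Xs[i, ])
      for (k in seq_len(npar)) {
        ek <- basis[[if (k <= nb) k else k - nb]]
        cik <- if (k <= nb) d[i] else 1
        if (cik == 0) next
        m <- vi %*% ek %*% vi
        trV[k] <- trV[k] + cik * sum(vi * ek)
        Tk[[k]] <- Tk[[k]] + cik * kronecker(m, xx)
      }
    }
    for (k in seq_len(npar)) {
      ek <- basis[[if (k <= nb) k else k - nb]]
      cvec <- if (k <= nb) d else rep(1, n)
      wk <- (R %*% ek) * cvec            # rows c_ik * E_k r_i
      Wk[[k]] <- wk
      quad <- sum(R * wk)                # y'P Ddot_k P y
      trP <- trV[k] - sum(W_inv * Tk[[k]])
      grad[k] <- -0.5 * (trP - quad)
    }
    # AI matrix: 0.5 * w_k' P w_l
    Vw <- vector("list", npar)           # V^-1 w_k rows
    XtVw <- matrix(0, np, npar)
    for (k in seq_len(npar)) {
      vw <- matrix(0, n, t_n)
      for (i in seq_len(n)) vw[i, ] <- Vi_inv[[i]] %*% Wk[[k]][i, ]
      Vw[[k]] <- vw
      acc <- numeric(np)
      for (i in seq_len(n)) acc <- acc + kronecker(vw[i, ], Xs[i, ])
      XtVw[, k] <- acc
    }
    AI <- matrix(0, npar, npar)
    WiX <- W_inv %*% XtVw
    for (k in seq_len(npar)) {
      for (l in k:npar) {
        AI[k, l] <- AI[l, k] <-
          0.5 * (sum(Wk[[k]] * Vw[[l]]) - sum(XtVw[, k] * WiX[, l]))
      }
    }
    list(loglik = loglik, grad = grad, AI = AI, R = R, Vi_inv = Vi_inv,
         W_inv = W_inv, Xs = Xs)
  }

  em_step <- function(Va, Ve, cur) {
    R <- cur$R; Vi_inv <- cur$Vi_inv; W_inv <- cur$W_inv; Xs <- cur$Xs
    Va_acc <- matrix(0, t_n, t_n)
    Ve_acc <- matrix(0, t_n, t_n)
    for (i in seq_len(n)) {
      xi <- Xs[i, ]
      # B_i = (I x xi') W^-1 (I x xi): t x t
      Bi <- matrix(0, t_n, t_n)
      for (m1 in seq_len(t_n)) {
        idx1 <- (m1 - 1L) * p + seq_len(p)
        for (m2 in m1:t_n) {
          idx2 <- (m2 - 1L) * p + seq_len(p)
          Bi[m1, m2] <- Bi[m2, m1] <- xi %*% W_inv[idx1, idx2] %*% xi
        }
      }
      Pii <- Vi_inv[[i]] - Vi_inv[[i]] %*% Bi %*% Vi_inv[[i]]
      ri <- R[i, ]
      Va_acc <- Va_acc + d[i] * (Va %*% tcrossprod(ri) %*% Va) + Va -
        d[i] * (Va %*% Pii %*% Va)
      Ve_acc <- Ve_acc + (Ve %*% tcrossprod(ri) %*% Ve) + Ve -
        Ve %*% Pii %*% Ve
    }
    list(Va = symmpart_dense(Va_acc / n), Ve = symmpart_dense(Ve_acc / n))
  }

  list(derivs = derivs, em_step = em_step)
}

# ---------------------------------------------------------------------------
# general path: dense V over the observed cells
reml_general_machinery <- function(design, K) {
  t_n <- length(design$traits)
  obs <- design$obs
  n <- nrow(obs)
  cells <- which(t(obs))                 # cell index in the full (n*t) grid,
                                         # trait-within-record ordering
  n_cells <- length(cells)
  y_full <- as.vector(t(design$y))
  y_obs <- y_full[cells]
  p <- ncol(design$X)
  # fixed design over observed cells, trait-major coefficient blocks
  Xc <- matrix(0, n_cells, t_n * p)
  rec_of <- ((cells - 1L) %/% t_n) + 1L
  trt_of <- ((cells - 1L) %% t_n) + 1L
  for (cidx in seq_len(n_cells)) {
    cols <- (trt_of[cidx] - 1L) * p + seq_len(p)
    Xc[cidx, cols] <- design$X[rec_of[cidx], ]
  }
  basis <- vech_basis(t_n)
  nb <- length(basis)
  npar <- 2L * nb
  # dV/dtheta_k over observed cells
  dV <- vector("list", npar)
  Ione <- diag(n)
  for (k in seq_len(nb)) {
    dV[[k]] <- kronecker(K, basis[[k]])[cells, cells, drop = FALSE]
    dV[[k + nb]] <- kronecker(Ione, basis[[k]])[cells, cells, drop = FALSE]
  }

  derivs <- function(Va, Ve) {
    V <- kronecker(K, Va)[cells, cells, drop = FALSE] +
      kronecker(Ione, Ve)[cells, cells, drop = FALSE]
    ch <- tryCatch(chol(symmpart_dense(V)), error = function(e) NULL)
    if (is.null(ch)) return(list(loglik = -Inf))
    V_inv <- chol2inv(ch)
    XtVi <- crossprod(Xc, V_inv)
    W <- XtVi %*% Xc
    chW <- tryCatch(chol(symmpart_dense(W)), error = function(e) NULL)
    if (is.null(chW)) return(list(loglik = -Inf))
    W_inv <- chol2inv(chW)
    P <- V_inv - t(XtVi) %*% W_inv %*% XtVi
    P <- symmpart_dense(P)
    Py <- as.vector(P %*% y_obs)
    loglik <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chW))) +
                        sum(y_obs * Py))
    grad <- numeric(npar)
    PdV <- vector("list", npar)
    w <- vector("list", npar)
    for (k in seq_len(npar)) {
      w[[k]] <- as.vector(dV[[k]] %*% Py)
      grad[k] <- -0.5 * (sum(P * dV[[k]]) - sum(Py * w[[k]]))
    }
    AI <- matrix(0, npar, npar)
    Pw <- vapply(w, function(wk) as.vector(P %*% wk), numeric(n_cells))
    for (k in seq_len(npar)) {
      for (l in k:npar) {
        AI[k, l] <- AI[l, k] <- 0.5 * sum(w[[k]] * Pw[, l])
      }
    }
    list(loglik = loglik, grad = grad, AI = AI, P = P, Py = Py)
  }

  K_inv <- chol2inv(chol(symmpart_dense(K) + diag(1e-10, n)))
  S_expand <- function(v) {               # observed cells -> full n*t grid
    full <- numeric(n * t_n)
    full[cells] <- v
    full
  }

  em_step <- function(Va, Ve, cur) {
    P <- cur$P; Py <- cur$Py
    # U-hat (n x t): u = (K x Va) S' Py
    PyF <- matrix(S_expand(Py), nrow = t_n)      # t x n (trait-major cols)
    Uhat <- K %*% t(PyF) %*% Va                  # n x t
    # C = S' P S on the full grid, as a (n*t) x (n*t) block structure
    Cfull <- matrix(0, n * t_n, n * t_n)
    Cfull[cells, cells] <- P
    # M = sum_{c,d} K_{cd} C_{dc} (t x t block contraction)
    M <- matrix(0, t_n, t_n)
    N <- matrix(0, t_n, t_n)
    for (a in seq_len(n)) {
      ia <- (a - 1L) * t_n + seq_len(t_n)
      N <- N + Cfull[ia, ia]
      for (b in seq_len(n)) {
        if (K[a, b] == 0) next
        ib <- (b - 1L) * t_n + seq_len(t_n)
        M <- M + K[b, a] * Cfull[ia, ib]
      }
    }
    Va_new <- (crossprod(Uhat, K_inv) %*% Uhat + n * Va -
                 Va %*% M %*% Va) / n
    # residuals: e-hat = Ve S' Py per record
    Ehat <- t(PyF) %*% Ve                        # n x t
    Ve_new <- (crossprod(Ehat) + n * Ve - Ve %*% N %*% Ve) / n
    list(Va = symmpart_dense(Va_new), Ve = symmpart_dense(Ve_new))
  }

  list(derivs = derivs, em_step = em_step)
}

# ---------------------------------------------------------------------------
# broom-style accessors

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a REML fit
#'
#' One row per free (co)variance parameter, plus derived heritabilities and
#' genetic/residual correlations.
#'
#' @param x `ssgwas_reml` object.
#' @param ... Unused.
#' @return Tibble with `component` (`additive`/`residual`/`derived`),
#'   `trait1`, `trait2`, `quantity`, `estimate`.
#' @export
tidy.ssgwas_reml <- function(x, ...) {
  tr <- x$traits
  t_n <- length(tr)
  ij <- which(lower.tri(diag(t_n), diag = TRUE), arr.ind = TRUE)
  cov_rows <- function(m, comp) {
    tibble(component = comp, trait1 = tr[ij[, 2]], trait2 = tr[ij[, 1]],
           quantity = ifelse(ij[, 1] == ij[, 2], "variance", "covariance"),
           estimate = m[ij])
  }
  h2 <- diag(x$Va) / (diag(x$Va) + diag(x$Ve))
  derived <- tibble(component = "derived", trait1 = tr, trait2 = tr,
                    quantity = "heritability", estimate = h2)
  corr_rows <- function(m, comp) {
    off <- ij[ij[, 1] != ij[, 2], , drop = FALSE]
    if (nrow(off) == 0L) return(NULL)
    tibble(component = "derived", trait1 = tr[off[, 2]], trait2 = tr[off[, 1]],
           quantity = paste0(comp, "_correlation"),
           estimate = m[off] / sqrt(diag(m)[off[, 1]] * diag(m)[off[, 2]]))
  }
  dplyr::bind_rows(cov_rows(x$Va, "additive"), cov_rows(x$Ve, "residual"),
                   derived, corr_rows(x$Va, "genetic"),
                   corr_rows(x$Ve, "residual"))
}

#' Glance at a REML fit
#'
#' @param x `ssgwas_reml` object.
#' @param ... Unused.
#' @return One-row tibble: log-likelihood, iterations, convergence flag,
#'   record count, EM fallback count.
#' @export
glance.ssgwas_reml <- function(x, ...) {
  tibble(loglik = x$loglik, n_iter = x$n_iter, converged = x$converged,
         n_records = x$n_records,
         n_em_steps = sum(x$trace$step == "EM"))
}

#' @exportS3Method base::print
print.ssgwas_reml <- function(x, ...) {
  cat(sprintf("<ssgwas_reml> %d traits, %d records; logL = %.4f after %d iterations\n",
              length(x$traits), x$n_records, x$loglik, x$n_iter))
  cat("Va:\n"); print(round(x$Va, 5))
  cat("Ve:\n"); print(round(x$Ve, 5))
  invisible(x)
}

#' Plot the REML iteration trace
#'
#' @param object `ssgwas_reml` object.
#' @param ... Unused.
#' @return A ggplot of restricted log-likelihood against iteration, colored
#'   by step type (AI vs EM).
#' @export
autoplot.ssgwas_reml <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$iteration, y = .data$loglik)) +
    ggplot2::geom_line(color = "grey60") +
    ggplot2::geom_point(ggplot2::aes(color = .data$step)) +
    ggplot2::labs(x = "iteration", y = "restricted log-likelihood",
                  color = "step") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
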