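#' Genomic relationship matrix from dosages
#'
#' Standard allele-frequency-standardized estimator:
#' `A_jk = (1/M) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`
#' with `p_i` the sample allele frequency of SNP `i`. SNPs that are fixed or
#' below the MAF floor are excluded.
#'
#' @param genotypes A `genotype_matrix` or dosage matrix (individuals x SNPs,
#'   rownames = ids).
#' @param maf_floor Minimum minor allele frequency (default 0.01).
#' @return A `grm` object: list with `A` (symmetric matrix with id dimnames)
#'   and `n_snps` used.
#' @export
compute_grm <- function(genotypes, maf_floor = 0.01) {
  D <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosage else genotypes
  p <- colMeans(D) / 2
  maf <- pmin(p, 1 - p)
  keep <- maf >= maf_floor & p > 0 & p < 1
  abort_if(sum(keep) < 1, "no SNPs left after MAF filtering")
  Z <- sweep(D[, keep, drop = FALSE], 2, 2 * p[keep], `-`)
  Z <- sweep(Z, 2, sqrt(2 * p[keep] * (1 - p[keep])), `/`)
  A <- tcrossprod(Z) / sum(keep)
  structure(list(A = A, ids = rownames(D), n_snps = sum(keep)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("<grm> ", nrow(x$A), " individuals, ", x$n_snps, " SNPs\n", sep = "")
  invisible(x)
}

# Eigendecomposition of a GRM restricted to `ids`, with bending: eigenvalues
# below -1e-8 are reported (the Gram-matrix estimator is PSD up to rounding)
# and tiny negative values are clipped to zero.
grm_eigen <- function(grm, ids = NULL) {
  A <- grm$A
  if (!is.null(ids)) A <- A[ids, ids, drop = FALSE]
  eg <- eigen(A, symmetric = TRUE)
  if (min(eg$values) < -1e-8) {
    message("GRM bent: smallest eigenvalue ", format(min(eg$values)),
            " clipped to 0")
  }
  eg$values <- pmax(eg$values, 0)
  eg
}

psd_project <- function(M, floor = 0) {
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  eg$vectors %*% (pmax(eg$values, floor) * t(eg$vectors))
}

# ---- AI-REML in the GRM eigenbasis -----------------------------------------
#
# After rotating by the GRM eigenvectors U, V = G (x) K + R (x) I becomes
# block diagonal with d x d blocks V_i = lambda_i G + R, and the only fixed
# effect (a per-trait intercept) rotates to xt = U'1. Every REML quantity
# (P y, traces, the AI matrix) is then O(n d^2) per iteration.
#
# Parameters: d = 1 -> theta = (V_A, V_E); d = 2 -> theta =
# (g11, g12, g22, e11, e12, e22).

reml_eigen_core <- function(Yt, xt, lam, max_iter = 100, tol = 1e-6,
                            em_iter = 3) {
  d <- ncol(Yt)
  n <- nrow(Yt)
  S <- cov(Yt)  # rotation is orthogonal, so this is on the trait scale
  floor_e <- 1e-8 * mean(diag(S))
  G0 <- psd_project(S / 2, 0)
  # shrink the residual start towards its diagonal so V is PD even for
  # perfectly correlated traits
  R0 <- psd_project(0.9 * S / 2 + 0.1 * diag(diag(S), d) / 2,
                    1e-3 * mean(diag(S)))
  theta <- if (d == 1) c(G0[1, 1], R0[1, 1]) else
    c(G0[1, 1], G0[1, 2], G0[2, 2], R0[1, 1], R0[1, 2], R0[2, 2])

  unpack <- function(th) {
    if (d == 1) {
      list(G = matrix(th[1]), R = matrix(th[2]))
    } else {
      list(G = matrix(th[c(1, 2, 2, 3)], 2), R = matrix(th[c(4, 5, 5, 6)], 2))
    }
  }
  pack <- function(G, R) {
    if (d == 1) c(G[1, 1], R[1, 1]) else
      c(G[1, 1], G[1, 2], G[2, 2], R[1, 1], R[1, 2], R[2, 2])
  }
  project <- function(th) {
    gr <- unpack(th)
    pack(psd_project(gr$G, 0), psd_project(gr$R, floor_e))
  }

  # Returns NULL when V is not PD; otherwise the state needed by ll/grad/AI.
  decompose <- function(th) {
    gr <- unpack(th)
    G <- gr$G; R <- gr$R
    if (d == 1) {
      v <- lam * G[1, 1] + R[1, 1]
      if (any(v <= 0)) return(NULL)
      W11 <- 1 / v; W12 <- numeric(n); W22 <- numeric(n)
      logdet <- sum(log(v))
    } else {
      V11 <- lam * G[1, 1] + R[1, 1]
      V12 <- lam * G[1, 2] + R[1, 2]
      V22 <- lam * G[2, 2] + R[2, 2]
      det <- V11 * V22 - V12^2
      if (any(V11 <= 0) || any(det <= 0)) return(NULL)
      W11 <- V22 / det; W12 <- -V12 / det; W22 <- V11 / det
      logdet <- sum(log(det))
    }
    x2 <- xt^2
    if (d == 1) {
      Q <- matrix(sum(x2 * W11))
      Qi <- matrix(1 / Q[1, 1])
      by <- sum(xt * W11 * Yt[, 1])
      beta <- Qi %*% by
      E1 <- Yt[, 1] - xt * beta[1]
      u1 <- W11 * E1; u2 <- numeric(n); E2 <- numeric(n)
      ypy <- sum(E1 * u1)
      logdetQ <- log(Q[1, 1])
    } else {
      Q <- matrix(c(sum(x2 * W11), sum(x2 * W12),
                    sum(x2 * W12), sum(x2 * W22)), 2)
      Qi <- solve(Q)
      by <- c(sum(xt * (W11 * Yt[, 1] + W12 * Yt[, 2])),
              sum(xt * (W12 * Yt[, 1] + W22 * Yt[, 2])))
      beta <- drop(Qi %*% by)
      E1 <- Yt[, 1] - xt * beta[1]
      E2 <- Yt[, 2] - xt * beta[2]
      u1 <- W11 * E1 + W12 * E2
      u2 <- W12 * E1 + W22 * E2
      ypy <- sum(E1 * u1 + E2 * u2)
      logdetQ <- determinant(Q, logarithm = TRUE)$modulus[1]
    }
    ll <- -0.5 * (logdet + logdetQ + ypy)
    list(G = G, R = R, W11 = W11, W12 = W12, W22 = W22, Qi = Qi,
         u1 = u1, u2 = u2, ll = ll)
  }

  # trace terms T = sum_i w_i * Wt_i with Wt = W - x^2 W Qi W, and
  # data terms M = sum_i w_i * u_i u_i', for weights w = lam (genetic) or 1.
  trace_data <- function(st) {
    W11 <- st$W11; W12 <- st$W12; W22 <- st$W22
    Qi <- st$Qi; u1 <- st$u1; u2 <- st$u2
    x2 <- xt^2
    if (d == 1) {
      WQW11 <- W11 * Qi[1, 1] * W11
      Wt11 <- W11 - x2 * WQW11
      list(
        T_G = matrix(sum(lam * Wt11)), T_R = matrix(sum(Wt11)),
        M_G = matrix(sum(lam * u1^2)), M_R = matrix(sum(u1^2))
      )
    } else {
      q11 <- Qi[1, 1]; q12 <- Qi[1, 2]; q22 <- Qi[2, 2]
      t1 <- W11 * q11 + W12 * q12; t2 <- W11 * q12 + W12 * q22
      s1 <- W12 * q11 + W22 * q12; s2 <- W12 * q12 + W22 * q22
      WQW11 <- t1 * W11 + t2 * W12
      WQW12 <- t1 * W12 + t2 * W22
      WQW22 <- s1 * W12 + s2 * W22
      Wt11 <- W11 - x2 * WQW11
      Wt12 <- W12 - x2 * WQW12
      Wt22 <- W22 - x2 * WQW22
      sy <- function(a11, a12, a22, w) matrix(c(sum(w * a11), sum(w * a12),
                                                sum(w * a12), sum(w * a22)), 2)
      list(
        T_G = sy(Wt11, Wt12, Wt22, lam), T_R = sy(Wt11, Wt12, Wt22, 1),
        M_G = sy(u1 * u1, u1 * u2, u2 * u2, lam),
        M_R = sy(u1 * u1, u1 * u2, u2 * u2, 1)
      )
    }
  }

  vechd <- function(A) if (d == 1) A[1, 1] else
    c(A[1, 1], 2 * A[1, 2], A[2, 2])

  grad_fun <- function(td) {
    -0.5 * c(vechd(td$T_G) - vechd(td$M_G), vechd(td$T_R) - vechd(td$M_R))
  }

  ai_fun <- function(st) {
    u1 <- st$u1; u2 <- st$u2
    W11 <- st$W11; W12 <- st$W12; W22 <- st$W22
    Qi <- st$Qi
    # v_k = Vdot_k u for each parameter; columns (v^1, v^2) per trait
    if (d == 1) {
      vs <- list(cbind(lam * u1, 0), cbind(u1, 0))
    } else {
      vs <- list(
        cbind(lam * u1, numeric(n)),          # g11
        cbind(lam * u2, lam * u1),            # g12
        cbind(numeric(n), lam * u2),          # g22
        cbind(u1, numeric(n)),                # e11
        cbind(u2, u1),                        # e12
        cbind(numeric(n), u2)                 # e22
      )
    }
    Wv <- function(v) cbind(W11 * v[, 1] + W12 * v[, 2],
                            W12 * v[, 1] + W22 * v[, 2])
    Pv <- lapply(vs, function(v) {
      tvec <- c(sum(xt * (W11 * v[, 1] + W12 * v[, 2])),
                sum(xt * (W12 * v[, 1] + W22 * v[, 2])))[seq_len(d)]
      cvec <- drop(Qi %*% tvec)
      if (d == 1) {
        Wv(cbind(v[, 1] - xt * cvec[1], 0))
      } else {
        Wv(cbind(v[, 1] - xt * cvec[1], v[, 2] - xt * cvec[2]))
      }
    })
    np <- length(vs)
    AI <- matrix(0, np, np)
    for (k in seq_len(np)) for (l in k:np) {
      AI[k, l] <- AI[l, k] <- 0.5 * sum(vs[[k]] * Pv[[l]])
    }
    AI
  }

  em_step <- function(th, td) {
    gr <- unpack(th)
    G <- gr$G + gr$G %*% (td$M_G - td$T_G) %*% gr$G / n
    R <- gr$R + gr$R %*% (td$M_R - td$T_R) %*% gr$R / n
    project(pack(G, R))
  }

  st <- decompose(theta)
  abort_if(is.null(st), "initial variance structure not positive definite")
  ll <- st$ll
  converged <- FALSE
  iter <- 0L
  AI <- NULL
  grad <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    td <- trace_data(st)
    grad <- grad_fun(td)
    if (iter <= em_iter) {
      theta_new <- em_step(theta, td)
    } else {
      AI <- ai_fun(st)
      delta <- tryCatch(solve(AI + diag(1e-10, nrow(AI)), grad),
                        error = function(e) NULL)
      theta_new <- NULL
      if (!is.null(delta)) {
        step <- 1
        for (h in 1:20) {
          cand <- project(theta + step * delta)
          stc <- decompose(cand)
          if (!is.null(stc) && stc$ll >= ll - 1e-12) {
            theta_new <- cand
            break
          }
          step <- step / 2
        }
      }
      if (is.null(theta_new)) theta_new <- em_step(theta, td)
    }
    st_new <- decompose(theta_new)
    if (is.null(st_new)) break
    if (abs(st_new$ll - ll) < tol && iter > em_iter) {
      theta <- theta_new; st <- st_new; ll <- st_new$ll
      converged <- TRUE
      break
    }
    theta <- theta_new; st <- st_new; ll <- st_new$ll
  }
  td <- trace_data(st)
  grad <- grad_fun(td)
  AI <- ai_fun(st)
  se <- tryCatch(sqrt(pmax(diag(solve(AI)), 0)), error = function(e)
    rep(NA_real_, length(theta)))
  list(theta = theta, G = unpack(theta)$G, R = unpack(theta)$R, ll = ll,
       converged = converged, iter = iter, grad = grad, AI = AI, se = se)
}

reml_prepare <- function(traits, grm) {
  ids <- rownames(grm$A)
  for (y in traits) ids <- intersect(ids, names(y)[!is.na(y)])
  abort_if(length(ids) < 30, "need >= 30 individuals with traits and GRM")
  eg <- grm_eigen(grm, ids)
  Y <- vapply(traits, function(y) as.numeric(scale(y[ids])), numeric(length(ids)))
  list(ids = ids, eg = eg, Yt = crossprod(eg$vectors, Y),
       xt = drop(crossprod(eg$vectors, rep(1, length(ids)))))
}

#' Univariate REML heritability with a GRM
#'
#' Average-information REML (with initial EM steps and step-halving on
#' likelihood decreases) for the model `y = mu + g + e`,
#' `g ~ N(0, V_A * GRM)`, `e ~ N(0, V_E * I)`. The trait is standardized to
#' unit variance, so components are on the phenotypic-variance scale and
#' `h2 = V_A / (V_A + V_E)`. Solved in the GRM eigenbasis (O(n) per
#' iteration after one eigendecomposition).
#'
#' An optional common-family environmental component `V_f` (a family-block
#' covariance) is supported through a generic dense solver.
#'
#' @param trait Named numeric vector.
#' @param grm A `grm` object.
#' @param max_iter,tol Iteration cap (default 100) and log-likelihood
#'   convergence tolerance (default 1e-6).
#' @param family Optional named factor/character vector of family ids; when
#'   given, a `V_f` component is added.
#' @return A `reml_fit`: `V_A`, `V_E` (and `V_f`), `h2`, `se_h2`, `loglik`,
#'   `converged`, `n`, `grad` (score at the final estimate).
#' @export
univariate_reml <- function(trait, grm, max_iter = 100, tol = 1e-6,
                            family = NULL) {
  if (!is.null(family)) {
    return(reml_family(trait, grm, family, max_iter = max_iter, tol = tol))
  }
  pr <- reml_prepare(list(trait), grm)
  fit <- reml_eigen_core(pr$Yt, pr$xt, pr$eg$values,
                         max_iter = max_iter, tol = tol)
  va <- fit$G[1, 1]; ve <- fit$R[1, 1]
  h2 <- va / (va + ve)
  # delta method for h2 from the AI-based covariance of (V_A, V_E)
  se_h2 <- tryCatch({
    Vc <- solve(fit$AI)
    gr <- c(ve, -va) / (va + ve)^2
    sqrt(max(drop(t(gr) %*% Vc %*% gr), 0))
  }, error = function(e) NA_real_)
  structure(list(V_A = va, V_E = ve, h2 = h2, se_h2 = se_h2,
                 loglik = fit$ll, converged = fit$converged, iter = fit$iter,
                 grad = fit$grad, AI = fit$AI, n = length(pr$ids),
                 kind = "univariate"),
            class = "reml_fit")
}

#' Bivariate REML genetic correlation with a GRM
#'
#' AI-REML for the two-trait model with genetic covariance `G (x) GRM` and
#' residual covariance `R (x) I` (3 + 3 parameters). Both traits are
#' standardized to unit variance. The genetic correlation
#' `rG = cov_A / sqrt(V_A1 * V_A2)` is constrained to \[-1, 1\] through PSD
#' projection of `G`; when either trait's genetic variance converges to the
#' zero boundary, `rG` is reported as `NA` with `boundary = TRUE`.
#'
#' @inheritParams univariate_reml
#' @param trait1,trait2 Named numeric vectors on overlapping individuals.
#' @return A `reml_fit` with `G`, `R`, per-trait `h2`, `rG`, `se_rG`,
#'   `loglik`, `converged`, `boundary`, `n`.
#' @export
bivariate_reml <- function(trait1, trait2, grm, max_iter = 100, tol = 1e-6) {
  pr <- reml_prepare(list(trait1, trait2), grm)
  fit <- reml_eigen_core(pr$Yt, pr$xt, pr$eg$values,
                         max_iter = max_iter, tol = tol)
  make_bivariate_fit(fit, length(pr$ids))
}

make_bivariate_fit <- function(fit, n) {
  G <- fit$G; R <- fit$R
  va1 <- G[1, 1]; va2 <- G[2, 2]; cva <- G[1, 2]
  vp1 <- va1 + R[1, 1]; vp2 <- va2 + R[2, 2]
  boundary <- va1 < 1e-6 * vp1 || va2 < 1e-6 * vp2
  rg <- if (boundary) NA_real_ else
    max(-1, min(1, cva / sqrt(va1 * va2)))
  se_rg <- if (boundary) NA_real_ else tryCatch({
    Vc <- solve(fit$AI)[1:3, 1:3]
    gr <- c(-cva / (2 * va1), 1, -cva / (2 * va2)) / sqrt(va1 * va2)
    sqrt(max(drop(t(gr) %*% Vc %*% gr), 0))
  }, error = function(e) NA_real_)
  structure(list(G = G, R = R,
                 V_A1 = va1, V_A2 = va2, cov_A = cva,
                 h2_1 = va1 / vp1, h2_2 = va2 / vp2,
                 rG = rg, se_rG = se_rg, boundary = boundary,
                 loglik = fit$ll, converged = fit$converged, iter = fit$iter,
                 grad = fit$grad, AI = fit$AI, n = n, kind = "bivariate"),
            class = "reml_fit")
}

# Generic dense REML (Cholesky solves) for models with extra components,
# currently V = V_A * K + V_f * F + V_E * I with F a family-block indicator.
reml_family <- function(trait, grm, family, max_iter = 100, tol = 1e-6) {
  ids <- intersect(rownames(grm$A), names(trait)[!is.na(trait)])
  abort_if(length(ids) < 30, "need >= 30 individuals")
  abort_if(is.null(names(family)), "`family` must be named by individual id")
  y <- as.numeric(scale(trait[ids]))
  n <- length(y)
  K <- grm$A[ids, ids]
  fam <- family[ids]
  Fm <- outer(fam, fam, `==`) * 1
  Clist <- list(V_A = K, V_f = Fm, V_E = diag(n))
  X <- matrix(1, n, 1)
  theta <- c(V_A = 1 / 3, V_f = 1 / 3, V_E = 1 / 3)
  eval_state <- function(th) {
    V <- th[1] * Clist[[1]] + th[2] * Clist[[2]] + th[3] * Clist[[3]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vi <- chol2inv(ch)
    ViX <- Vi %*% X
    Q <- crossprod(X, ViX)
    Qi <- solve(Q)
    P <- Vi - ViX %*% Qi %*% t(ViX)
    u <- drop(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(ch))) + determinant(Q, TRUE)$modulus[1] +
                    sum(y * u))
    list(P = P, u = u, ll = ll)
  }
  st <- eval_state(theta)
  ll <- st$ll
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    PC <- lapply(Clist, function(C) st$P %*% C)
    grad <- vapply(seq_along(Clist), function(k)
      -0.5 * (sum(diag(PC[[k]])) - drop(crossprod(st$u, Clist[[k]] %*% st$u))),
      numeric(1))
    Cu <- lapply(Clist, function(C) drop(C %*% st$u))
    AI <- matrix(0, 3, 3)
    for (k in 1:3) for (l in k:3) {
      AI[k, l] <- AI[l, k] <- 0.5 * drop(crossprod(Cu[[k]], st$P %*% Cu[[l]]))
    }
    delta <- tryCatch(solve(AI + diag(1e-10, 3), grad), error = function(e)
      grad / max(abs(grad)) * 0.1)
    step <- if (iter <= 3) 0.3 else 1
    repeat {
      cand <- pmax(theta + step * delta, 1e-8)
      stc <- eval_state(cand)
      if (!is.null(stc) && stc$ll >= ll - 1e-10) break
      step <- step / 2
      if (step < 1e-6) { cand <- theta; stc <- st; break }
    }
    done <- abs(stc$ll - ll) < tol
    theta <- cand; st <- stc; ll <- stc$ll
    if (done) { converged <- TRUE; break }
  }
  vp <- sum(theta)
  structure(list(V_A = theta[[1]], V_f = theta[[2]], V_E = theta[[3]],
                 h2 = theta[[1]] / vp, se_h2 = NA_real_,
                 loglik = ll, converged = converged, iter = iter,
                 grad = NULL, n = n, kind = "univariate-family"),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("<reml_fit> ", x$kind, ", n = ", x$n,
      ", converged = ", x$converged, "\n", sep = "")
  if (x$kind == "bivariate") {
    cat("  h2:", signif(x$h2_1, 3), "/", signif(x$h2_2, 3),
        "  rG:", signif(x$rG, 3), "(se", signif(x$se_rG, 2), ")\n")
  } else {
    cat("  V_A:", signif(x$V_A, 3), " V_E:", signif(x$V_E, 3),
        " h2:", signif(x$h2, 3), "\n")
  }
  invisible(x)
}

#' Genetic correlations for a batch of probe pairs
#'
#' Runs [bivariate_reml()] for each expression/methylation probe pair;
#' failures and boundary fits are recorded, not fatal. The GRM is
#' eigendecomposed once per unique individual set.
#'
#' @param pairs Tibble with `expr_probe` and `meth_probe` columns.
#' @param expr,meth `trait_matrix` objects (methylation is transformed to M
#'   values for fitting when `kind == "methylation"`).
#' @param grm A `grm` object.
#' @param max_iter,tol Passed to the fitter.
#' @return Tibble with per-pair `rG`, `se_rG`, `h2_expr`, `h2_meth`,
#'   `converged`, `boundary`, `loglik`, `n`.
#' @export
batch_genetic_correlations <- function(pairs, expr, meth, grm,
                                       max_iter = 100, tol = 1e-6) {
  if (nrow(pairs) == 0) {
    return(tibble(expr_probe = character(), meth_probe = character(),
                  rG = numeric(), se_rG = numeric(), h2_expr = numeric(),
                  h2_meth = numeric(), converged = logical(),
                  boundary = logical(), loglik = numeric(), n = integer()))
  }
  Ve <- expr$values
  Vm <- if (identical(meth$kind, "methylation")) beta_to_m(meth$values) else
    meth$values
  # with complete data all pairs share one individual set: eigendecompose once
  # (ids ordered as in the GRM, matching the single-pair code path exactly)
  ids <- intersect(rownames(grm$A), intersect(colnames(Ve), colnames(Vm)))
  complete <- !anyNA(Ve[pairs$expr_probe, ids]) && !anyNA(Vm[pairs$meth_probe, ids])
  eg <- if (complete) grm_eigen(grm, ids) else NULL
  xt <- if (complete) drop(crossprod(eg$vectors, rep(1, length(ids)))) else NULL
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    y1 <- Ve[pairs$expr_probe[i], ]
    y2 <- Vm[pairs$meth_probe[i], ]
    fit <- tryCatch({
      if (complete) {
        Y <- cbind(as.numeric(scale(y1[ids])), as.numeric(scale(y2[ids])))
        core <- reml_eigen_core(crossprod(eg$vectors, Y), xt, eg$values,
                                max_iter = max_iter, tol = tol)
        make_bivariate_fit(core, length(ids))
      } else {
        bivariate_reml(y1, y2, grm, max_iter = max_iter, tol = tol)
      }
    }, error = function(e) NULL)
    if (is.null(fit)) {
      tibble(expr_probe = pairs$expr_probe[i], meth_probe = pairs$meth_probe[i],
             rG = NA_real_, se_rG = NA_real_, h2_expr = NA_real_,
             h2_meth = NA_real_, converged = FALSE, boundary = NA,
             loglik = NA_real_, n = NA_integer_)
    } else {
      tibble(expr_probe = pairs$expr_probe[i], meth_probe = pairs$meth_probe[i],
             rG = fit$rG, se_rG = fit$se_rG, h2_expr = fit$h2_1,
             h2_meth = fit$h2_2, converged = fit$converged,
             boundary = fit$boundary, loglik = fit$loglik,
             n = as.integer(fit$n))
    }
  })
  bind_rows(rows)
}
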