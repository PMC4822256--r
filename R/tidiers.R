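#' Tidy a REML fit
#'
#' @param x A `reml_fit` from [univariate_reml()] or [bivariate_reml()].
#' @param ... Unused.
#' @return A tibble with one row per (co)variance component (`term`,
#'   `estimate`).
#' @export
tidy.reml_fit <- function(x, ...) {
  if (x$kind == "bivariate") {
    tibble(
      term = c("V_A1", "cov_A", "V_A2", "V_E1", "cov_E", "V_E2"),
      estimate = c(x$G[1, 1], x$G[1, 2], x$G[2, 2],
                   x$R[1, 1], x$R[1, 2], x$R[2, 2])
    )
  } else {
    terms <- c("V_A", if (!is.null(x$V_f)) "V_f", "V_E")
    tibble(term = terms,
           estimate = c(x$V_A, if (!is.null(x$V_f)) x$V_f, x$V_E))
  }
}

#' Glance at a REML fit
#'
#' @inheritParams tidy.reml_fit
#' @return One-row tibble with the headline quantities: heritabilities,
#'   genetic correlation (bivariate), log-likelihood, convergence, `n`.
#' @export
glance.reml_fit <- function(x, ...) {
  if (x$kind == "bivariate") {
    tibble(h2_1 = x$h2_1, h2_2 = x$h2_2, rG = x$rG, se_rG = x$se_rG,
           boundary = x$boundary, logLik = x$loglik,
           converged = x$converged, n = x$n)
  } else {
    tibble(h2 = x$h2, se_h2 = x$se_h2, logLik = x$loglik,
           converged = x$converged, n = x$n)
  }
}
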