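#' Fisher-Z asymptotic p-value for a Pearson correlation
#'
#' Under bivariate normality, `atanh(r)` is approximately normal with
#' variance `1/(n-3)`, giving the two-sided asymptotic p-value
#' `p = 2 * Phi_bar(|atanh(r)| * sqrt(n-3))` for H0: rho = 0. Computed in log
#' space so values far below 1e-12 do not underflow prematurely.
#'
#' @param r Pearson correlation(s) in \[-1, 1\].
#' @param n Sample size(s); must be >= 4.
#' @return Two-sided p-value(s) in (0, 1\]; exactly 0 (with a warning flag)
#'   only when `|r| = 1`.
#' @export
#' @examples
#' fisher_z_pvalue(0.27, 610)
fisher_z_pvalue <- function(r, n) {
  abort_if(any(n < 4), "`n` must be >= 4 for the asymptotic p-value")
  abort_if(any(abs(r) > 1, na.rm = TRUE), "`r` must lie in [-1, 1]")
  degenerate <- !is.na(r) & abs(r) == 1
  if (any(degenerate)) {
    warning("p = 0 returned for ", sum(degenerate), " correlation(s) with |r| = 1")
  }
  z <- abs(atanh(ifelse(degenerate, 0, r))) * sqrt(n - 3)
  p <- exp(pnorm(z, lower.tail = FALSE, log.p = TRUE) + log(2))
  p <- pmin(p, 1)
  p[degenerate] <- 0
  p
}

#' Bonferroni family-wise p-value threshold
#'
#' @param n_tests Number of tests in the family.
#' @param alpha Family-wise error rate, in (0, 1).
#' @return `alpha / n_tests`.
#' @export
#' @examples
#' bonferroni_threshold(16659 * 303078)  # ~9.9e-12
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  abort_if(n_tests < 1, "`n_tests` must be >= 1")
  abort_if(alpha <= 0 || alpha >= 1, "`alpha` must be in (0, 1)")
  alpha / n_tests
}

#' Smallest absolute correlation significant at a p-value cutoff
#'
#' Inverts the Fisher-Z test: the boundary correlation is
#' `tanh(z* / sqrt(n-3))` with `z*` the two-sided standard-normal quantile at
#' `p_cut`. A bisection solver over [fisher_z_pvalue()] is available as an
#' independent route; both agree to 1e-10.
#'
#' @param n Sample size (>= 4).
#' @param p_cut Two-sided p-value threshold in (0, 1).
#' @param method `"closed_form"` (default) or `"bisection"`.
#' @return Smallest `|r|` with `fisher_z_pvalue(r, n) <= p_cut`.
#' @export
#' @examples
#' min_significant_r(610, bonferroni_threshold(16659 * 303078))  # ~0.27
min_significant_r <- function(n, p_cut, method = c("closed_form", "bisection")) {
  abort_if(n < 4, "`n` must be >= 4")
  abort_if(p_cut <= 0 || p_cut >= 1, "`p_cut` must be in (0, 1)")
  method <- match.arg(method)
  if (method == "closed_form") {
    zstar <- qnorm(p_cut / 2, lower.tail = FALSE)
    tanh(zstar / sqrt(n - 3))
  } else {
    lo <- 0; hi <- 1 - 1e-15
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (fisher_z_pvalue(mid, n) <= p_cut) hi <- mid else lo <- mid
    }
    hi
  }
}

#' Exhaustive block-wise cross-correlation of two trait matrices
#'
#' Computes pairwise-complete Pearson correlations between every expression
#' probe and every methylation probe, with Fisher-Z p-values, iterating over
#' blocks of probe indices so that the full cross-correlation matrix is never
#' held in memory at once. The emitted pair set is identical for any block
#' partition. Pairs whose pairwise-complete sample size falls below `min_n`
#' are dropped, and probes with zero variance in the used subsample are
#' skipped; both are tallied in attributes `"dropped_low_n"` and
#' `"skipped_zero_var"` of the result.
#'
#' @param expr,meth `trait_matrix` objects or probes x individuals matrices
#'   sharing (a subset of) individual ids as column names.
#' @param block Integer vector `c(expression_block, methylation_block)` of
#'   block sizes in probes.
#' @param p_cut Emit only pairs with `p <= p_cut` (default 1: all).
#' @param r_cut Emit only pairs with `|r| >= r_cut` (default 0: all).
#' @param min_n Minimum pairwise-complete sample size (default 10; the
#'   asymptotic p-value is not meaningful below that).
#' @return Tibble with columns `expr_probe`, `meth_probe`, `r`, `n`, `p`.
#' @export
cross_correlate <- function(expr, meth, block = c(2000L, 5000L),
                            p_cut = 1, r_cut = 0, min_n = 10L) {
  X <- if (inherits(expr, "trait_matrix")) expr$values else expr
  Y <- if (inherits(meth, "trait_matrix")) meth$values else meth
  ids <- intersect(colnames(X), colnames(Y))
  abort_if(length(ids) < 4, "fewer than 4 shared individuals")
  X <- X[, ids, drop = FALSE]
  Y <- Y[, ids, drop = FALSE]
  abort_if(any(block < 1), "block sizes must be >= 1")
  min_n <- max(min_n, 4L)

  row_blocks <- split(seq_len(nrow(X)), ceiling(seq_len(nrow(X)) / block[1]))
  col_blocks <- split(seq_len(nrow(Y)), ceiling(seq_len(nrow(Y)) / block[2]))
  dropped_low_n <- 0L
  skipped_zero_var <- 0L
  out <- list()

  for (rb in row_blocks) {
    Xb <- X[rb, , drop = FALSE]
    Mx <- !is.na(Xb); X0 <- Xb; X0[!Mx] <- 0
    storage.mode(Mx) <- "double"
    for (cb in col_blocks) {
      Yb <- Y[cb, , drop = FALSE]
      My <- !is.na(Yb); Y0 <- Yb; Y0[!My] <- 0
      storage.mode(My) <- "double"
      nn <- tcrossprod(Mx, My)
      Sx <- tcrossprod(X0, My); Sy <- tcrossprod(Mx, Y0)
      Sxx <- tcrossprod(X0 * X0, My); Syy <- tcrossprod(Mx, Y0 * Y0)
      Sxy <- tcrossprod(X0, Y0)
      ok_n <- nn >= min_n
      dropped_low_n <- dropped_low_n + sum(!ok_n)
      cv <- Sxy - Sx * Sy / nn
      vx <- Sxx - Sx * Sx / nn
      vy <- Syy - Sy * Sy / nn
      zero <- ok_n & (vx <= 0 | vy <= 0)
      skipped_zero_var <- skipped_zero_var + sum(zero)
      r <- cv / sqrt(pmax(vx, 0) * pmax(vy, 0))
      r <- pmin(pmax(r, -1), 1)
      use <- ok_n & !zero
      if (!any(use)) next
      idx <- which(use, arr.ind = TRUE)
      ri <- r[idx]; ni <- nn[idx]
      pi <- fisher_z_pvalue(ri, ni)
      keep <- pi <= p_cut & abs(ri) >= r_cut
      if (!any(keep)) next
      out[[length(out) + 1L]] <- tibble(
        expr_probe = rownames(Xb)[idx[keep, 1]],
        meth_probe = rownames(Yb)[idx[keep, 2]],
        r = ri[keep], n = as.integer(ni[keep]), p = pi[keep]
      )
    }
  }
  res <- if (length(out)) bind_rows(out) else
    tibble(expr_probe = character(), meth_probe = character(),
           r = numeric(), n = integer(), p = numeric())
  res <- arrange(res, .data$expr_probe, .data$meth_probe)
  attr(res, "dropped_low_n") <- dropped_low_n
  attr(res, "skipped_zero_var") <- skipped_zero_var
  res
}

#' Annotate probe pairs with chromosomal relationship and distance
#'
#' Distance is between probe midpoints; a pair is `cis` when both probes sit
#' on the same chromosome within `cis_window` bp (closed boundary: distance
#' equal to the window counts as cis) and `trans` otherwise. Pairs with a
#' probe missing from the annotation are labelled `unplaced` and carry no
#' distance.
#'
#' @param pairs Tibble with `expr_probe` and `meth_probe` columns (e.g. from
#'   [cross_correlate()]).
#' @param expr_annot,meth_annot Tibbles with `probe`, `chrom`, `start`, `end`.
#' @param cis_window Window in bp (default 5e5).
#' @return `pairs` with added `chrom_e`, `chrom_m`, `same_chromosome`,
#'   `distance`, `class` columns.
#' @export
pair_distance_and_class <- function(pairs, expr_annot, meth_annot,
                                    cis_window = 5e5) {
  mid <- function(a) mutate(a, .mid = (.data$start + .data$end) / 2)
  ea <- mid(expr_annot) %>% select(probe = "probe", chrom_e = "chrom", mid_e = ".mid")
  ma <- mid(meth_annot) %>% select(probe = "probe", chrom_m = "chrom", mid_m = ".mid")
  pairs %>%
    left_join(ea, by = c(expr_probe = "probe")) %>%
    left_join(ma, by = c(meth_probe = "probe")) %>%
    mutate(
      same_chromosome = .data$chrom_e == .data$chrom_m,
      distance = ifelse(.data$same_chromosome,
                        abs(.data$mid_e - .data$mid_m), NA_real_),
      class = case_when(
        is.na(.data$chrom_e) | is.na(.data$chrom_m) ~ "unplaced",
        .data$same_chromosome & .data$distance <= cis_window ~ "cis",
        TRUE ~ "trans"
      )
    ) %>%
    select(-"mid_e", -"mid_m")
}
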