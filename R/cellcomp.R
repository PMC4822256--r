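#' Observed cell proportions from differential counts
#'
#' Converts per-individual nucleated blood cell counts into proportions by
#' dividing each count by the individual's total across all counted types.
#'
#' @param counts Individuals x cell-types matrix (or data frame) of
#'   non-negative counts, with individual rownames.
#' @return A `cell_props` object with provenance `"observed"`; individuals
#'   with a zero total are set to `NA` and flagged with a warning.
#' @export
observed_proportions <- function(counts) {
  m <- as.matrix(counts)
  abort_if(any(m < 0, na.rm = TRUE), "counts must be non-negative")
  tot <- rowSums(m)
  zero <- !is.finite(tot) | tot == 0
  if (any(zero)) {
    warning(sum(zero), " individual(s) with zero total count set to NA")
  }
  p <- m / tot
  p[zero, ] <- NA_real_
  new_cell_props(p, "observed")
}

#' Rank probes by cell-type specificity with a moderated one-vs-rest t
#'
#' For each cell type, every probe is scored by a two-sample pooled-variance
#' t statistic contrasting that cell type's reference replicates against all
#' other reference samples, with the per-probe pooled variance shrunk toward
#' the across-probe mean variance:
#' `s2_mod = (d0 * s2_bar + d * s2) / (d0 + d)` with residual df `d` and
#' prior weight `d0` (default 4, i.e. the prior counts as four
#' pseudo-samples). Rank 1 is the most differential probe by `|t|`; probes
#' constant across all samples get `t = 0` and rank last.
#'
#' @param reference Probes x reference-samples matrix of beta values.
#' @param cell_types Cell identity of each reference sample (>= 2 replicates
#'   per type).
#' @param prior_n Prior weight `d0` of the variance shrinkage (0 = plain
#'   pooled t).
#' @return Tibble (`probe`, `cell_type`, `t`, `rank`) with one row per probe
#'   per cell type.
#' @export
rank_celltype_markers <- function(reference, cell_types, prior_n = 4) {
  abort_if(ncol(reference) != length(cell_types),
           "`cell_types` must have one entry per reference sample")
  tab <- table(cell_types)
  abort_if(any(tab < 2), "need >= 2 replicate samples per cell type")
  types <- names(tab)
  out <- lapply(types, function(ct) {
    in1 <- cell_types == ct
    n1 <- sum(in1); n0 <- sum(!in1)
    m1 <- rowMeans(reference[, in1, drop = FALSE])
    m0 <- rowMeans(reference[, !in1, drop = FALSE])
    v1 <- apply(reference[, in1, drop = FALSE], 1, var)
    v0 <- apply(reference[, !in1, drop = FALSE], 1, var)
    d <- n1 + n0 - 2
    s2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / d
    s2_mod <- (prior_n * mean(s2) + d * s2) / (prior_n + d)
    tt <- (m1 - m0) / sqrt(s2_mod * (1 / n1 + 1 / n0))
    tt[!is.finite(tt)] <- 0
    tibble(probe = rownames(reference), cell_type = ct, t = tt) %>%
      arrange(desc(abs(.data$t)), .data$probe) %>%
      mutate(rank = row_number())
  })
  bind_rows(out) %>% arrange(.data$cell_type, .data$rank)
}

#' Build a deconvolution reference profile from marker ranks
#'
#' Takes the union of the top-`k_per_type` probes per cell type, optionally
#' intersected with the probes available in the target dataset, and stores
#' the mean reference beta per cell type for each selected probe.
#'
#' @param ranks Tibble from [rank_celltype_markers()].
#' @param reference Probes x reference-samples beta matrix (same probes).
#' @param cell_types Cell identity per reference sample.
#' @param k_per_type Specificity-rank cutoff (default 70).
#' @param available Optional character vector of probes present in the target
#'   dataset; selected probes outside it are dropped with a message.
#' @return A `reference_profile`: list with `profile` (selected probes x cell
#'   types mean-beta matrix), `selected` (tibble of probe/cell_type/rank for
#'   the selecting ranks) and `k_per_type`.
#' @export
build_reference_matrix <- function(ranks, reference, cell_types,
                                   k_per_type = 70, available = NULL) {
  abort_if(k_per_type < 1, "`k_per_type` must be >= 1")
  sel <- filter(ranks, .data$rank <= k_per_type)
  probes <- sort(unique(sel$probe))
  if (!is.null(available)) {
    keep <- probes %in% available
    if (any(!keep)) {
      message(sum(!keep), " selected probe(s) absent from the target dataset; ",
              sum(keep), " retained")
    }
    probes <- probes[keep]
  }
  abort_if(length(probes) == 0, "no selected probes available in the target dataset")
  types <- sort(unique(cell_types))
  prof <- vapply(types, function(ct)
    rowMeans(reference[probes, cell_types == ct, drop = FALSE]), numeric(length(probes)))
  prof <- matrix(prof, nrow = length(probes),
                 dimnames = list(probes, types))
  structure(list(profile = prof, selected = sel, k_per_type = k_per_type),
            class = "reference_profile")
}

#' Predict cell proportions from methylation by reference-based deconvolution
#'
#' Regresses each individual's beta values over the selected marker probes on
#' the reference mean-beta columns by ordinary least squares with no
#' intercept and no constraints: predicted proportions may be negative and
#' need not sum to one.
#'
#' @param beta Probes x individuals beta matrix (or `trait_matrix`); must
#'   contain the reference profile's probes.
#' @param reference A `reference_profile` from [build_reference_matrix()].
#' @return A `cell_props` with provenance `"predicted-raw"`.
#' @export
predict_proportions <- function(beta, reference) {
  B <- if (inherits(beta, "trait_matrix")) beta$values else beta
  R <- reference$profile
  probes <- intersect(rownames(R), rownames(B))
  abort_if(length(probes) < ncol(R),
           "need at least as many usable probes as cell types")
  R <- R[probes, , drop = FALSE]
  qrR <- qr(R)
  if (qrR$rank < ncol(R)) {
    cc <- cor(R)
    bad <- unique(colnames(R)[which(abs(cc) > 1 - 1e-10 & row(cc) < col(cc),
                                    arr.ind = TRUE)])
    stop("reference profile is rank-deficient; collinear cell types: ",
         paste(if (length(bad)) bad else colnames(R), collapse = ", "),
         call. = FALSE)
  }
  coefs <- qr.coef(qrR, B[probes, , drop = FALSE])
  pred <- t(coefs)
  colnames(pred) <- colnames(R)
  new_cell_props(pred, "predicted-raw")
}

#' Calibrate predicted proportions against observed proportions
#'
#' Applies a per-cell-type affine map to the predictions such that, on the
#' overlapping individuals, the regression of (calibrated) predicted values
#' on observed values has slope one and intercept zero — putting the
#' predictions on the observed-proportion scale.
#'
#' @param predicted A `cell_props` with predicted proportions.
#' @param observed A `cell_props` with observed proportions; >= 3 individuals
#'   must overlap.
#' @return A `cell_props` with provenance `"predicted-calibrated"` and the
#'   per-type `(intercept, slope)` of the fitted map in `$calibration`.
#'   Cell types with zero-variance predictions are passed through unchanged
#'   with a warning.
#' @export
calibrate_predictions <- function(predicted, observed) {
  pm <- predicted$props
  om <- observed$props
  ids <- intersect(rownames(pm), rownames(om))
  ids <- ids[complete.cases(om[ids, , drop = FALSE])]
  abort_if(length(ids) < 3, "need >= 3 overlapping individuals to calibrate")
  types <- intersect(colnames(pm), colnames(om))
  out <- pm
  cal <- tibble(cell_type = types, intercept = NA_real_, slope = NA_real_)
  for (j in seq_along(types)) {
    ct <- types[j]
    x <- om[ids, ct]; y <- pm[ids, ct]
    if (var(y) == 0 || var(x) == 0) {
      warning("zero-variance predictions or observations for ", ct,
              "; calibration skipped")
      next
    }
    b <- cov(y, x) / var(x)
    a <- mean(y) - b * mean(x)
    if (b == 0) {
      warning("zero slope for ", ct, "; calibration skipped")
      next
    }
    out[, ct] <- (pm[, ct] - a) / b
    cal$intercept[j] <- a; cal$slope[j] <- b
  }
  new_cell_props(out, "predicted-calibrated", calibration = cal)
}

#' Adjust traits for cell composition
#'
#' Replaces each probe's values by the residuals of an ordinary least squares
#' regression on the cell-proportion columns plus an intercept. Individuals
#' without proportions are dropped. When the proportions sum exactly to one
#' (observed proportions) the design is collinear with the intercept; the
#' largest-mean cell type column is then dropped with a warning (the fitted
#' subspace, hence the residuals, are unchanged by which column goes).
#'
#' @param trait A `trait_matrix` or probes x individuals matrix. Methylation
#'   should be adjusted on the M scale (see [beta_to_m()]).
#' @param proportions A `cell_props` (or individuals x types matrix).
#' @return Adjusted traits of the same class, restricted to individuals with
#'   proportions; residuals are orthogonal to the design.
#' @export
adjust_for_proportions <- function(trait, proportions) {
  tm <- inherits(trait, "trait_matrix")
  V <- if (tm) trait$values else trait
  P <- if (inherits(proportions, "cell_props")) proportions$props else proportions
  ids <- intersect(colnames(V), rownames(P))
  ids <- ids[complete.cases(P[ids, , drop = FALSE])]
  abort_if(length(ids) <= ncol(P) + 1, "too few individuals with proportions")
  V <- V[, ids, drop = FALSE]
  P <- P[ids, , drop = FALSE]
  X <- cbind(`(Intercept)` = 1, P)
  if (qr(X)$rank < ncol(X)) {
    drop_ct <- colnames(P)[which.max(colMeans(P))]
    warning("proportions collinear with intercept; dropping column '",
            drop_ct, "'")
    X <- X[, setdiff(colnames(X), drop_ct), drop = FALSE]
  }
  qx <- qr(X)
  if (anyNA(V)) {
    res <- V
    for (i in seq_len(nrow(V))) {
      ok <- !is.na(V[i, ])
      if (sum(ok) > ncol(X)) {
        res[i, ok] <- qr.resid(qr(X[ok, , drop = FALSE]), V[i, ok])
      } else {
        res[i, ] <- NA_real_
      }
    }
  } else {
    res <- t(qr.resid(qx, t(V)))
  }
  dimnames(res) <- dimnames(V)
  if (tm) new_trait_matrix(res, trait$annot, trait$kind) else res
}

#' Fraction of confounder-driven correlation remaining after adjustment on a
#' noisy predictor
#'
#' Under a linear single-confounder model — two traits each loading on a
#' common proportion `c`, adjusted by residualizing on a predictor `c_hat`
#' with `cor(c_hat, c) = r_pred` — the confounder-driven covariance is
#' attenuated by exactly `1 - r_pred^2`: that fraction of the original
#' correlation (measured on the original trait scale) survives adjustment.
#'
#' @param r_pred Correlation between predicted and true proportions, in
#'   \[0, 1\].
#' @return `1 - r_pred^2`.
#' @seealso [simulate_residual_confounding()] for the direct simulation.
#' @export
#' @examples
#' residual_confounding_fraction(c(0.75, 0.95))  # ~0.44 and ~0.10
residual_confounding_fraction <- function(r_pred) {
  abort_if(any(r_pred < 0 | r_pred > 1), "`r_pred` must be in [0, 1]")
  1 - r_pred^2
}

#' Simulate the remaining confounded correlation after noisy-predictor
#' adjustment
#'
#' Direct Monte-Carlo check of [residual_confounding_fraction()]: draws a
#' latent proportion `c` and a predictor `c_hat` with the requested
#' correlation, builds replicate trait pairs `y = loading * c + noise`,
#' residualizes both traits of each pair on `c_hat`, and returns the ratio of
#' the post- to pre-adjustment correlation measured on the original trait
#' scale (i.e. the ratio of the summed covariances; re-standardizing by the
#' shrunken residual variances would equal this only in the weak-loading
#' limit).
#'
#' @param r_pred Predictor-truth correlation in \[0, 1\].
#' @param n Individuals per replicate pair (default 1e5).
#' @param n_pairs Number of replicate trait pairs to average over.
#' @param loading Confounder loading of each trait (unit-variance confounder,
#'   unit noise SD; default 0.5).
#' @param seed Integer seed.
#' @return Scalar remaining fraction in \[0, 1\].
#' @export
simulate_residual_confounding <- function(r_pred, n = 1e5, n_pairs = 25,
                                          loading = 0.5, seed = 1L) {
  abort_if(r_pred < 0 || r_pred > 1, "`r_pred` must be in [0, 1]")
  with_seed(seed, {
    cov_pre <- 0; cov_post <- 0
    for (k in seq_len(n_pairs)) {
      cc <- rnorm(n)
      chat <- r_pred * cc + sqrt(1 - r_pred^2) * rnorm(n)
      y1 <- loading * cc + rnorm(n)
      y2 <- loading * cc + rnorm(n)
      r1 <- residuals(lm.fit(cbind(1, chat), y1))
      r2 <- residuals(lm.fit(cbind(1, chat), y2))
      cov_pre <- cov_pre + cov(y1, y2)
      cov_post <- cov_post + cov(r1, r2)
    }
    cov_post / cov_pre
  })
}

#' Beta to M value transformation (and inverse)
#'
#' `M = log2(beta / (1 - beta))`, the logit2 scale on which methylation is
#' approximately homoscedastic. Beta values are clipped to
#' `[eps, 1 - eps]` before transforming.
#'
#' @param beta Beta value(s) in \[0, 1\].
#' @param eps Clipping bound (default 1e-6).
#' @return M value(s).
#' @export
#' @examples
#' beta_to_m(0.8)  # 2
beta_to_m <- function(beta, eps = 1e-6) {
  abort_if(any(beta < 0 | beta > 1, na.rm = TRUE), "`beta` must be in [0, 1]")
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' @rdname beta_to_m
#' @param m M value(s).
#' @export
m_to_beta <- function(m) {
  1 / (1 + 2^(-m))
}
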