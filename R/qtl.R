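#' Single-SNP association scan for one trait
#'
#' Ordinary least squares of the trait on each SNP dosage in turn, after
#' projecting out covariates (plus an intercept): slope, standard error,
#' two-sided t-test p-value and `R2` (the squared partial correlation,
#' `t^2 / (t^2 + df)`). Monomorphic SNPs (zero dosage variance among used
#' individuals) are skipped and tallied in attribute `"skipped_monomorphic"`.
#'
#' With a `grm`, a two-step generalized-least-squares mode is used instead:
#' variance components are first estimated by [univariate_reml()], then trait
#' and dosages are whitened by the fitted covariance before the per-SNP
#' regression — counteracting the test-statistic inflation that family
#' structure induces under plain OLS.
#'
#' @param trait Named numeric vector of trait values (names = individual ids).
#' @param genotypes A `genotype_matrix` (or a dosage matrix with individual
#'   rownames and SNP colnames, in which case `snps` annotation is omitted).
#' @param covariates Optional individuals x covariates matrix.
#' @param grm Optional `grm` object switching on the GLS mode.
#' @param min_p Reporting floor for p-values (default 1e-300).
#' @return A tibble (`snp`, `chrom`, `pos`, `beta`, `se`, `p`, `r2`), one row
#'   per tested SNP.
#' @export
single_snp_assoc <- function(trait, genotypes, covariates = NULL,
                             grm = NULL, min_p = 1e-300) {
  D <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosage else genotypes
  snps <- if (inherits(genotypes, "genotype_matrix")) genotypes$snps else
    tibble(snp = colnames(D), chrom = NA_character_, pos = NA_real_)
  ids <- intersect(names(trait), rownames(D))
  ids <- ids[!is.na(trait[ids])]
  abort_if(length(ids) < 30, "need >= 30 individuals with trait and genotypes")
  y <- trait[ids]
  X <- D[ids, , drop = FALSE]
  C <- cbind(`(Intercept)` = rep(1, length(ids)),
             if (!is.null(covariates)) covariates[ids, , drop = FALSE])

  if (!is.null(grm)) {
    fit <- univariate_reml(y, grm)
    eg <- grm_eigen(grm, ids)
    w <- 1 / sqrt(fit$V_A * eg$values + fit$V_E)
    y <- w * drop(crossprod(eg$vectors, y))
    X <- w * crossprod(eg$vectors, X)
    C <- w * crossprod(eg$vectors, C)
  }

  qc <- qr(C)
  yr <- qr.resid(qc, y)
  Xr <- qr.resid(qc, X)
  q <- qc$rank
  n <- length(y)
  df <- n - q - 1
  sxx <- colSums(Xr^2)
  mono <- sxx <= 1e-12 * n
  sxy <- drop(crossprod(Xr, yr))
  syy <- sum(yr^2)
  keep <- !mono
  b <- unname(sxy[keep] / sxx[keep])
  sigma2 <- pmax(unname(syy - b * sxy[keep]), 0) / df
  se <- sqrt(sigma2 / unname(sxx[keep]))
  tt <- b / se
  p <- pmax(2 * pt(-abs(tt), df), min_p)
  r2 <- ifelse(is.finite(tt), tt^2 / (tt^2 + df), 1)
  res <- tibble(
    snp = colnames(X)[keep], beta = b, se = se, p = p, r2 = r2
  ) %>%
    left_join(snps[, c("snp", "chrom", "pos")], by = "snp") %>%
    select("snp", "chrom", "pos", "beta", "se", "p", "r2")
  if (any(mono)) {
    message(sum(mono), " monomorphic SNP(s) skipped")
  }
  attr(res, "skipped_monomorphic") <- sum(mono)
  attr(res, "n_used") <- n
  res
}

best_snp_record <- function(scan, relaxed_p) {
  cand <- filter(scan, .data$p < relaxed_p)
  if (nrow(cand) == 0) return(NULL)
  cand[which.min(cand$p), ]
}

#' Shared-QTL overlap between an expression and a methylation scan
#'
#' The shared set is the intersection of SNP ids passing the stringent
#' p-value cutoff in both scans. Best SNPs are the lowest-p SNPs under the
#' relaxed cutoff in each scan separately; the best-SNP distance is the bp
#' distance between them when both exist on the same chromosome.
#'
#' @param scan_e,scan_m Association scans from [single_snp_assoc()] over the
#'   same SNP panel.
#' @param stringent_p Cutoff defining a QTL (default 1e-5).
#' @param relaxed_p Cutoff for collecting the best SNP per probe
#'   (default 0.1).
#' @return One-row tibble: `n_shared`, `shared_snps` (list column),
#'   `best_esnp`, `best_msnp`, `best_distance`, `same_best_snp`.
#' @export
shared_qtl <- function(scan_e, scan_m, stringent_p = 1e-5, relaxed_p = 0.1) {
  shared <- intersect(scan_e$snp[scan_e$p < stringent_p],
                      scan_m$snp[scan_m$p < stringent_p])
  be <- best_snp_record(scan_e, relaxed_p)
  bm <- best_snp_record(scan_m, relaxed_p)
  bd <- if (!is.null(be) && !is.null(bm) &&
            !is.na(be$chrom) && identical(be$chrom, bm$chrom)) {
    abs(be$pos - bm$pos)
  } else {
    NA_real_
  }
  tibble(
    n_shared = length(shared),
    shared_snps = list(shared),
    best_esnp = if (is.null(be)) NA_character_ else be$snp,
    best_msnp = if (is.null(bm)) NA_character_ else bm$snp,
    best_distance = bd,
    same_best_snp = !is.null(be) && !is.null(bm) && identical(be$snp, bm$snp)
  )
}

#' Variance explained by a SNP
#'
#' Squared Pearson correlation between a trait and a dosage vector over
#' pairwise-complete observations.
#'
#' @param trait,dosage Numeric vectors of equal length.
#' @return `R^2` in \[0, 1\].
#' @export
variance_explained <- function(trait, dosage) {
  cor(trait, dosage, use = "pairwise.complete.obs")^2
}

#' Merge genomic intervals into regions
#'
#' Intervals on the same chromosome whose gap is at most `gap` bp are merged
#' into one region.
#'
#' @param chrom,start,end Parallel vectors defining intervals.
#' @param gap Maximum merge distance in bp (default 1e6).
#' @return Tibble (`chrom`, `start`, `end`, `n_members`), one row per region.
#' @export
merge_genomic_regions <- function(chrom, start, end, gap = 1e6) {
  d <- tibble(chrom = chrom, start = start, end = end) %>%
    arrange(.data$chrom, .data$start, .data$end)
  out <- list()
  for (cc in unique(d$chrom)) {
    di <- d[d$chrom == cc, ]
    cur_s <- di$start[1]; cur_e <- di$end[1]; cur_n <- 1L
    if (nrow(di) > 1) {
      for (i in 2:nrow(di)) {
        if (di$start[i] <= cur_e + gap) {
          cur_e <- max(cur_e, di$end[i]); cur_n <- cur_n + 1L
        } else {
          out[[length(out) + 1L]] <- tibble(chrom = cc, start = cur_s,
                                            end = cur_e, n_members = cur_n)
          cur_s <- di$start[i]; cur_e <- di$end[i]; cur_n <- 1L
        }
      }
    }
    out[[length(out) + 1L]] <- tibble(chrom = cc, start = cur_s, end = cur_e,
                                      n_members = cur_n)
  }
  bind_rows(out)
}

#' Summarise shared-QTL records over same-chromosome probe pairs
#'
#' @param records Tibble with one row per probe pair carrying at least
#'   `n_shared`, `best_distance`, `distance` (probe-probe bp distance),
#'   `same_best_snp` and, for region counting, `chrom`, `start`, `end` (the
#'   pair's genomic span). Typically assembled by [run_pipeline()] from
#'   [shared_qtl()] and [pair_distance_and_class()] output; may also carry
#'   `r`.
#' @param window Window for the "located within" fractions (default 1 Mb).
#' @param merge_dist Region merge distance (default 1 Mb).
#' @return A list: pair counts and sharing fraction, within-window fractions
#'   of probe-probe and best-SNP distances split by sharing status, mean
#'   `|r|` by sharing status (when `r` present), number of merged genomic
#'   regions among sharing pairs, and count of pairs with identical best SNP.
#' @export
summarize_shared_qtl <- function(records, window = 1e6, merge_dist = 1e6) {
  if (nrow(records) == 0) {
    return(list(n_pairs = 0L, n_sharing = 0L, frac_sharing = NA_real_,
                frac_within_window = c(sharing = NA_real_, nonsharing = NA_real_),
                frac_best_within_window = c(sharing = NA_real_, nonsharing = NA_real_),
                mean_abs_r = c(sharing = NA_real_, nonsharing = NA_real_),
                n_same_best_snp = 0L, n_regions = 0L))
  }
  sh <- records$n_shared > 0
  frac_within <- function(x) if (any(!is.na(x))) mean(x <= window, na.rm = TRUE) else NA_real_
  res <- list(
    n_pairs = nrow(records),
    n_sharing = sum(sh),
    frac_sharing = mean(sh),
    frac_within_window = c(
      sharing = frac_within(records$distance[sh]),
      nonsharing = frac_within(records$distance[!sh])
    ),
    frac_best_within_window = c(
      sharing = frac_within(records$best_distance[sh]),
      nonsharing = frac_within(records$best_distance[!sh])
    ),
    mean_abs_r = c(
      sharing = if ("r" %in% names(records)) mean(abs(records$r[sh])) else NA_real_,
      nonsharing = if ("r" %in% names(records)) mean(abs(records$r[!sh])) else NA_real_
    ),
    n_same_best_snp = sum(records$same_best_snp[sh], na.rm = TRUE)
  )
  res$n_regions <- if (any(sh) && all(c("chrom", "start", "end") %in% names(records))) {
    nrow(merge_genomic_regions(records$chrom[sh], records$start[sh],
                               records$end[sh], gap = merge_dist))
  } else {
    0L
  }
  res
}
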