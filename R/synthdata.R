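#' Simulate a twin-family pedigree
#'
#' Generates a cohort of nuclear families, each with two unrelated parents,
#' one twin pair (monozygotic or dizygotic) and a variable number of
#' additional full siblings — the family structure of classical blood
#' expression/methylation twin cohorts. Roughly half the twin pairs are MZ.
#'
#' @param n_families Number of families to simulate.
#' @param family_spec List controlling family composition:
#'   `p_mz`, the probability that the twin pair is monozygotic (default 0.5),
#'   and `sib_probs`, a probability vector over 0, 1, 2, ... extra full
#'   siblings (default `c(0.25, 0.30, 0.45)`, mean 1.2, so the average family
#'   has ~5.2 members and 117 families give ~610 individuals).
#' @param seed Integer seed; the pedigree is reproducible bit-for-bit.
#'
#' @return A tibble with one row per individual: `id`, `family`, `father`,
#'   `mother` (`NA` for founders), `role` (`"parent"`, `"mz"`, `"dz"`,
#'   `"sib"`), `sex` (`"M"`/`"F"`) and `mz_group` (shared integer for the two
#'   members of an MZ pair, `NA` otherwise). Parents precede their offspring.
#' @export
#' @examples
#' ped <- simulate_pedigree(2, seed = 1)
simulate_pedigree <- function(n_families,
                              family_spec = list(),
                              seed = 1L) {
  abort_if(n_families < 1, "`n_families` must be >= 1")
  spec <- modifyList(list(p_mz = 0.5, sib_probs = c(0.25, 0.30, 0.45)),
                     family_spec)
  abort_if(any(spec$sib_probs < 0) || sum(spec$sib_probs) <= 0,
           "`family_spec$sib_probs` must be non-negative and sum > 0")
  abort_if(spec$p_mz < 0 || spec$p_mz > 1, "`family_spec$p_mz` must be in [0,1]")
  sib_probs <- spec$sib_probs / sum(spec$sib_probs)

  with_seed(seed, {
    mz_group_counter <- 0L
    rows <- lapply(seq_len(n_families), function(f) {
      fam <- sprintf("F%03d", f)
      father <- paste0(fam, "_P1")
      mother <- paste0(fam, "_P2")
      is_mz <- runif(1) < spec$p_mz
      n_sib <- sample.int(length(sib_probs), 1, prob = sib_probs) - 1L
      kid_roles <- c(rep(if (is_mz) "mz" else "dz", 2), rep("sib", n_sib))
      kid_ids <- paste0(fam, "_C", seq_along(kid_roles))
      if (is_mz) mz_group_counter <<- mz_group_counter + 1L
      twin_sex <- sample(c("M", "F"), 1)
      kid_sex <- c(
        if (is_mz) rep(twin_sex, 2) else sample(c("M", "F"), 2, replace = TRUE),
        sample(c("M", "F"), n_sib, replace = TRUE)
      )
      tibble(
        id = c(father, mother, kid_ids),
        family = fam,
        father = c(NA, NA, rep(father, length(kid_ids))),
        mother = c(NA, NA, rep(mother, length(kid_ids))),
        role = c("parent", "parent", kid_roles),
        sex = c("M", "F", kid_sex),
        mz_group = c(NA, NA,
                     if (is_mz) rep(mz_group_counter, 2) else rep(NA, 2),
                     rep(NA, n_sib))
      )
    })
    bind_rows(rows)
  })
}

#' Simulate genotypes by gene dropping through a pedigree
#'
#' Founders receive Hardy-Weinberg genotypes at SNP-specific minor allele
#' frequencies; offspring receive one allele from each parent by an
#' independent Mendelian draw per SNP (no linkage). MZ twins get identical
#' genotypes. SNPs are laid out on chromosomes with uniform random positions.
#'
#' @param pedigree A tibble from [simulate_pedigree()].
#' @param n_snps Total number of SNPs.
#' @param maf_range Range from which per-SNP minor allele frequencies are
#'   drawn uniformly; must lie within (0, 0.5].
#' @param chrom_layout Named numeric vector of chromosome lengths in bp
#'   (default two 200 Mb autosomes); SNPs are split evenly across them.
#' @param seed Integer seed.
#'
#' @return An object of class `genotype_matrix`: a list with `dosage`
#'   (individuals x SNPs matrix of 0/1/2 allele counts, dimnames set),
#'   `snps` (tibble: `snp`, `chrom`, `pos`, `maf`) and `ids`.
#' @export
simulate_genotypes <- function(pedigree, n_snps,
                               maf_range = c(0.05, 0.5),
                               chrom_layout = c(`1` = 2e8, `2` = 2e8),
                               seed = 1L) {
  abort_if(n_snps < 1, "`n_snps` must be >= 1")
  abort_if(maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2],
           "`maf_range` must lie within (0, 0.5]")
  n <- nrow(pedigree)
  with_seed(seed, {
    maf <- runif(n_snps, maf_range[1], maf_range[2])
    chrom <- sort(rep(names(chrom_layout), length.out = n_snps))
    pos <- integer(n_snps)
    for (cc in unique(chrom)) {
      idx <- which(chrom == cc)
      pos[idx] <- sort(sample.int(chrom_layout[[cc]], length(idx)))
    }
    snp_id <- sprintf("snp%05d", seq_len(n_snps))

    # haplotype matrices: one paternal and one maternal allele per individual
    h1 <- matrix(0L, n, n_snps)
    h2 <- matrix(0L, n, n_snps)
    idx_of <- setNames(seq_len(n), pedigree$id)
    done_mz <- list()
    for (i in seq_len(n)) {
      fa <- pedigree$father[i]
      if (is.na(fa)) {
        h1[i, ] <- rbinom(n_snps, 1L, maf)
        h2[i, ] <- rbinom(n_snps, 1L, maf)
      } else {
        mzg <- pedigree$mz_group[i]
        if (!is.na(mzg) && !is.null(done_mz[[as.character(mzg)]])) {
          j <- done_mz[[as.character(mzg)]]
          h1[i, ] <- h1[j, ]
          h2[i, ] <- h2[j, ]
        } else {
          fi <- idx_of[[fa]]
          mi <- idx_of[[pedigree$mother[i]]]
          pick_f <- runif(n_snps) < 0.5
          pick_m <- runif(n_snps) < 0.5
          h1[i, ] <- ifelse(pick_f, h1[fi, ], h2[fi, ])
          h2[i, ] <- ifelse(pick_m, h1[mi, ], h2[mi, ])
          if (!is.na(mzg)) done_mz[[as.character(mzg)]] <- i
        }
      }
    }
    dosage <- h1 + h2
    dimnames(dosage) <- list(pedigree$id, snp_id)
    structure(
      list(
        dosage = dosage,
        snps = tibble(snp = snp_id, chrom = chrom, pos = pos, maf = maf),
        ids = pedigree$id
      ),
      class = "genotype_matrix"
    )
  })
}

#' Check Mendelian consistency of dosages against a pedigree
#'
#' For every offspring/SNP combination, checks that the dosage is attainable
#' from one allele of each parent (e.g. parents 0 and 2 can only produce a
#' heterozygote). Exhaustive; intended for validation at small scale.
#'
#' @param genotypes A `genotype_matrix`.
#' @param pedigree The pedigree the genotypes were simulated from.
#' @return Number of violating offspring-SNP combinations (0 = consistent).
#' @export
check_mendelian <- function(genotypes, pedigree) {
  d <- genotypes$dosage
  idx_of <- setNames(seq_len(nrow(pedigree)), pedigree$id)
  kids <- which(!is.na(pedigree$father))
  bad <- 0L
  for (i in kids) {
    df <- d[idx_of[[pedigree$father[i]]], ]
    dm <- d[idx_of[[pedigree$mother[i]]], ]
    lo <- (df == 2) + (dm == 2)                 # forced minor alleles
    hi <- 2L - ((df == 0) + (dm == 0))          # maximal minor alleles
    bad <- bad + sum(d[i, ] < lo | d[i, ] > hi)
  }
  bad
}

#' Blood cell-type panel and default base profile
#'
#' The eight nucleated blood cell types measured by differential counts,
#' with a neutrophil-dominant mean composition typical of adult whole blood.
#'
#' @return Named numeric vector of mean proportions summing to 1.
#' @export
blood_base_profile <- function() {
  c(Bcell = 0.06, CD4T = 0.15, CD8T = 0.08, NK = 0.05,
    Mono = 0.07, Eos = 0.03, Baso = 0.01, Neu = 0.55)
}

#' Simulate blood cell proportions
#'
#' Per-individual cell-type proportions drawn from a Dirichlet distribution
#' centred on a base profile. Higher `concentration` means less
#' between-individual variation (`Var(p_j) = p_j(1-p_j)/(concentration+1)`).
#'
#' @param pedigree A pedigree tibble (only ids are used).
#' @param concentration Dirichlet concentration (sum of alphas); default 40
#'   gives a neutrophil-proportion SD of ~0.08, typical of healthy adults.
#' @param base_profile Probability vector over cell types; default
#'   [blood_base_profile()].
#' @param seed Integer seed.
#' @return A `cell_props` object: list with `props` (individuals x cell types
#'   matrix, rows sum to 1) and `provenance = "observed-truth"`.
#' @export
simulate_cell_proportions <- function(pedigree, concentration = 40,
                                      base_profile = blood_base_profile(),
                                      seed = 1L) {
  abort_if(concentration <= 0, "`concentration` must be > 0")
  abort_if(abs(sum(base_profile) - 1) > 1e-8, "`base_profile` must sum to 1")
  with_seed(seed, {
    p <- rdirichlet(nrow(pedigree), concentration * base_profile)
    dimnames(p) <- list(pedigree$id, names(base_profile))
    new_cell_props(p, "observed-truth")
  })
}

new_cell_props <- function(props, provenance, calibration = NULL) {
  structure(list(props = props, provenance = provenance,
                 calibration = calibration),
            class = "cell_props")
}

#' @export
print.cell_props <- function(x, ...) {
  cat("<cell_props> ", nrow(x$props), " individuals x ", ncol(x$props),
      " cell types (", x$provenance, ")\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.cell_props <- function(x, ...) {
  as_tibble(x$props, rownames = "id")
}

#' Declare the composition of a synthetic expression/methylation cohort
#'
#' Collects the ground-truth generative settings for
#' [simulate_trait_matrices()]: how many probes are driven by blood cell
#' composition, how many expression/methylation pairs share a causal cis QTL
#' (and at what heritability and QTL effect size), how many load on a shared
#' latent factor emulating inflammation status, and how many are pure noise.
#'
#' @param n_expr,n_meth Total probes per platform.
#' @param n_cell_expr,n_cell_meth Probes whose variation is driven by a single
#'   dominant blood cell type (random type, random sign).
#' @param cell_var Fraction of trait variance explained by cell composition
#'   for cell-driven probes (default 0.6, enough that co-typed probe pairs
#'   correlate above the 0.5 graph cut before adjustment).
#' @param n_shared_pairs Number of planted expression-methylation probe pairs
#'   sharing one causal SNP within a cis window.
#' @param shared_h2 Total narrow-sense heritability of each shared-pair trait
#'   (default 0.6).
#' @param shared_qtl_var Fraction of trait variance explained by the shared
#'   causal SNP (default 0.4; the remainder of `shared_h2` is polygenic and
#'   independent between the pair members, so the implied true genetic
#'   correlation is `shared_qtl_var / shared_h2` in magnitude).
#' @param n_latent_expr,n_latent_meth Probes loading on the shared latent
#'   factor, with variance fraction `latent_var`.
#' @param latent_var Latent-factor variance fraction (default 0.3).
#' @param marker_noise_sd Beta-scale measurement noise of cell-type marker
#'   probes (used when marker profiles are supplied to
#'   [simulate_trait_matrices()]).
#' @param na_rate Missing-completely-at-random rate applied to emitted values.
#' @return A list of class `truth_spec`.
#' @export
truth_spec <- function(n_expr = 2000, n_meth = 5000,
                       n_cell_expr = 200, n_cell_meth = 500,
                       cell_var = 0.6,
                       n_shared_pairs = 50, shared_h2 = 0.6,
                       shared_qtl_var = 0.4,
                       n_latent_expr = 50, n_latent_meth = 100,
                       latent_var = 0.3,
                       marker_noise_sd = 0.02,
                       na_rate = 0) {
  spec <- as.list(environment())
  abort_if(n_cell_expr + n_shared_pairs + n_latent_expr > n_expr,
           "expression probe classes exceed `n_expr`")
  abort_if(n_cell_meth + n_shared_pairs + n_latent_meth > n_meth,
           "methylation probe classes exceed `n_meth`")
  abort_if(shared_qtl_var > shared_h2, "`shared_qtl_var` cannot exceed `shared_h2`")
  abort_if(cell_var < 0 || cell_var >= 1, "`cell_var` must be in [0,1)")
  abort_if(na_rate < 0 || na_rate >= 1, "`na_rate` must be in [0,1)")
  structure(spec, class = "truth_spec")
}

#' Simulate paired expression and methylation matrices with known truth
#'
#' Each probe value is a sum of a cell-composition term, a genetic term, a
#' latent-factor term and Gaussian noise, with the components rescaled so the
#' realized variance fractions match the declared truth. Methylation is
#' generated on the M scale and emitted as beta values in (0,1) through the
#' inverse logit2 transform; expression emulates normalized log2 intensities.
#'
#' @param genotypes A `genotype_matrix`.
#' @param proportions A `cell_props` object on the same individuals.
#' @param spec A [truth_spec()].
#' @param marker_profiles Optional markers x cell-types matrix of true
#'   purified-cell beta values (see [simulate_marker_profiles()]); when
#'   given, that many methylation probes are emitted as proportion-weighted
#'   mixtures of the profiles plus beta-scale noise, so reference-based
#'   deconvolution can recover the simulated proportions.
#' @param seed Integer seed.
#' @return A list with `expr` and `meth` (`trait_matrix` objects: `values`
#'   probes x individuals, `annot` tibble with `probe`,`chrom`,`start`,`end`,
#'   `kind`) and `truth` (a `truth_record`: per-probe classes/loadings/h2, the
#'   planted pair table with true genetic correlations, and the per-probe
#'   genetic values of heritable probes for post-hoc evaluation).
#' @export
simulate_trait_matrices <- function(genotypes, proportions,
                                    spec = truth_spec(),
                                    marker_profiles = NULL, seed = 1L) {
  abort_if(!inherits(spec, "truth_spec"), "`spec` must come from truth_spec()")
  d <- genotypes$dosage
  P <- proportions$props
  abort_if(nrow(d) != nrow(P) || !all(rownames(d) == rownames(P)),
           "genotypes and proportions must cover the same individuals")
  n <- nrow(d)
  types <- colnames(P)
  Pc <- scale(P, center = TRUE, scale = FALSE)
  n_marker <- if (is.null(marker_profiles)) 0L else nrow(marker_profiles)
  abort_if(spec$n_cell_meth + spec$n_shared_pairs + spec$n_latent_meth +
             n_marker > spec$n_meth,
           "methylation probe classes (incl. markers) exceed `n_meth`")

  with_seed(seed, {
    latent <- rnorm(n)  # shared inflammation-like factor

    make_cohort <- function(kind, n_tot, n_cell, n_latent, n_pairs, prefix,
                            n_mark = 0L) {
      cls <- c(rep("shared_qtl", n_pairs), rep("cell", n_cell),
               rep("latent", n_latent), rep("marker", n_mark),
               rep("null", n_tot - n_pairs - n_cell - n_latent - n_mark))
      tibble(
        probe = sprintf("%s%05d", prefix, seq_len(n_tot)),
        kind = kind, class = cls,
        cell_type = NA_character_, cell_sign = NA_real_,
        h2 = 0, causal_snp = NA_character_, latent_loading = 0
      )
    }
    expr_tab <- make_cohort("expression", spec$n_expr, spec$n_cell_expr,
                            spec$n_latent_expr, spec$n_shared_pairs, "e")
    meth_tab <- make_cohort("methylation", spec$n_meth, spec$n_cell_meth,
                            spec$n_latent_meth, spec$n_shared_pairs, "m",
                            n_marker)
    if (n_marker > 0) {
      tt <- attr(marker_profiles, "target_type")
      if (!is.null(tt)) {
        meth_tab$cell_type[meth_tab$class == "marker"] <- tt
      }
    }

    # plant shared-QTL pairs: one causal SNP each, probes placed in cis
    pair_snp_idx <- sample.int(ncol(d), spec$n_shared_pairs)
    pairs <- tibble(
      expr_probe = expr_tab$probe[seq_len(spec$n_shared_pairs)],
      meth_probe = meth_tab$probe[seq_len(spec$n_shared_pairs)],
      snp = genotypes$snps$snp[pair_snp_idx],
      chrom = genotypes$snps$chrom[pair_snp_idx],
      snp_pos = genotypes$snps$pos[pair_snp_idx],
      qtl_var = spec$shared_qtl_var, h2 = spec$shared_h2
    )
    sign_e <- sample(c(-1, 1), spec$n_shared_pairs, replace = TRUE)
    sign_m <- sample(c(-1, 1), spec$n_shared_pairs, replace = TRUE)
    pairs$true_rg <- sign_e * sign_m * spec$shared_qtl_var / spec$shared_h2

    n_poly <- min(50L, ncol(d))
    build_values <- function(tab, signs, kind) {
      vals <- matrix(0, nrow(tab), n,
                     dimnames = list(tab$probe, rownames(d)))
      gvals <- matrix(0, nrow(tab), n, dimnames = dimnames(vals))
      for (i in seq_len(nrow(tab))) {
        z <- rep(0, n); g <- rep(0, n); f_noise <- 1
        if (tab$class[i] == "cell") {
          ct <- sample(types, 1)
          sg <- sample(c(-1, 1), 1)
          tab$cell_type[i] <- ct; tab$cell_sign[i] <- sg
          z <- z + scale_to_sd(sg * Pc[, ct], sqrt(spec$cell_var))
          f_noise <- f_noise - spec$cell_var
        } else if (tab$class[i] == "latent") {
          lo <- sample(c(-1, 1), 1)
          tab$latent_loading[i] <- lo
          z <- z + scale_to_sd(lo * latent, sqrt(spec$latent_var))
          f_noise <- f_noise - spec$latent_var
        } else if (tab$class[i] == "shared_qtl") {
          s_idx <- pair_snp_idx[i]
          qtl <- scale_to_sd(signs[i] * d[, s_idx], sqrt(spec$shared_qtl_var))
          poly_idx <- sample.int(ncol(d), n_poly)
          poly <- scale_to_sd(drop(d[, poly_idx] %*% rnorm(n_poly)),
                              sqrt(spec$shared_h2 - spec$shared_qtl_var))
          g <- qtl + poly
          z <- z + g
          tab$h2[i] <- spec$shared_h2
          tab$causal_snp[i] <- genotypes$snps$snp[s_idx]
          f_noise <- f_noise - spec$shared_h2
        }
        z <- z + scale_to_sd(rnorm(n), sqrt(f_noise))
        vals[i, ] <- z
        gvals[i, ] <- g
      }
      list(tab = tab, values = vals,
           genetic = gvals[tab$class == "shared_qtl", , drop = FALSE])
    }

    eb <- build_values(expr_tab, sign_e, "expression")
    mb <- build_values(meth_tab, sign_m, "methylation")

    annotate <- function(tab, pair_pos, width) {
      chroms <- unique(genotypes$snps$chrom)
      lens <- vapply(chroms, function(cc)
        max(genotypes$snps$pos[genotypes$snps$chrom == cc]), numeric(1))
      k <- nrow(tab)
      chrom <- sample(chroms, k, replace = TRUE)
      mid <- vapply(seq_len(k), function(i)
        sample.int(lens[[chrom[i]]], 1), numeric(1))
      shared <- tab$class == "shared_qtl"
      chrom[shared] <- pairs$chrom
      mid[shared] <- pmax(width + 1,
                          pairs$snp_pos + round(runif(sum(shared), -2e5, 2e5)))
      tibble(probe = tab$probe, chrom = chrom,
             start = as.integer(mid - width), end = as.integer(mid + width))
    }
    expr_annot <- annotate(eb$tab, pairs$snp_pos, 25L)
    meth_annot <- annotate(mb$tab, pairs$snp_pos, 1L)

    # scale to platform-realistic units
    e_mu <- runif(spec$n_expr, 6, 10); e_sd <- runif(spec$n_expr, 0.8, 1.2)
    expr_vals <- eb$values * e_sd + e_mu
    m_mu <- runif(spec$n_meth, -3, 3); m_sd <- runif(spec$n_meth, 0.6, 1.2)
    meth_m <- mb$values * m_sd + m_mu
    meth_beta <- m_to_beta(meth_m)
    if (n_marker > 0) {
      mk <- which(mb$tab$class == "marker")
      mix <- marker_profiles %*% t(P[, colnames(marker_profiles)])
      mix <- mix + matrix(rnorm(length(mix), sd = spec$marker_noise_sd),
                          nrow(mix))
      meth_beta[mk, ] <- pmin(pmax(mix, 0.001), 0.999)
      rownames(marker_profiles) <- mb$tab$probe[mk]
    }

    if (spec$na_rate > 0) {
      expr_vals[runif(length(expr_vals)) < spec$na_rate] <- NA
      meth_beta[runif(length(meth_beta)) < spec$na_rate] <- NA
    }

    truth <- structure(
      list(
        probes = bind_rows(eb$tab, mb$tab),
        pairs = pairs,
        genetic_values = list(expr = eb$genetic * e_sd[seq_len(nrow(eb$genetic))],
                              meth = mb$genetic * m_sd[seq_len(nrow(mb$genetic))]),
        latent = latent,
        marker_profiles = marker_profiles,
        spec = spec
      ),
      class = "truth_record"
    )
    list(
      expr = new_trait_matrix(expr_vals, expr_annot, "expression"),
      meth = new_trait_matrix(meth_beta, meth_annot, "methylation"),
      truth = truth
    )
  })
}

#' Construct a trait matrix
#'
#' @param values Probes x individuals numeric matrix (rownames = probe ids).
#' @param annot Tibble with columns `probe`, `chrom`, `start`, `end` (BED-like,
#'   positions in bp), or `NULL`.
#' @param kind `"expression"` or `"methylation"` (methylation stored as beta).
#' @return A `trait_matrix` object.
#' @export
new_trait_matrix <- function(values, annot = NULL, kind = "expression") {
  abort_if(is.null(rownames(values)), "`values` must have probe rownames")
  structure(list(values = values, annot = annot, kind = kind),
            class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat("<trait_matrix> ", nrow(x$values), " ", x$kind, " probes x ",
      ncol(x$values), " individuals\n", sep = "")
  invisible(x)
}

#' Simulate true purified-cell beta profiles for marker probes
#'
#' Each marker probe is near-bimodal: a high (or low) beta in one target cell
#' type and the opposite level in all others, with per-probe jitter — the
#' pattern that makes blood cell types separable on methylation arrays.
#'
#' @param n_markers Number of marker probes (spread evenly over the types).
#' @param types Cell-type names (default the 8-type blood panel).
#' @param seed Integer seed.
#' @return Markers x types matrix of beta values in (0, 1), with attribute
#'   `"target_type"` giving each probe's target cell type.
#' @export
simulate_marker_profiles <- function(n_markers = 400,
                                     types = names(blood_base_profile()),
                                     seed = 1L) {
  abort_if(n_markers < length(types), "need at least one marker per type")
  with_seed(seed, {
    target <- rep(types, length.out = n_markers)
    hi <- runif(n_markers, 0.75, 0.95)
    lo <- runif(n_markers, 0.05, 0.25)
    flip <- runif(n_markers) < 0.5
    prof <- matrix(rep(ifelse(flip, hi, lo), length(types)),
                   nrow = n_markers)
    colnames(prof) <- types
    prof[cbind(seq_len(n_markers), match(target, types))] <-
      ifelse(flip, lo, hi)
    prof <- prof + matrix(rnorm(length(prof), sd = 0.02), n_markers)
    prof <- pmin(pmax(prof, 0.01), 0.99)
    rownames(prof) <- sprintf("mk%04d", seq_len(n_markers))
    attr(prof, "target_type") <- target
    prof
  })
}

#' Simulate purified-cell reference samples
#'
#' Replicate methylation samples of FACS-sorted cell types around the true
#' marker profiles. By default the basophil column is left out, mirroring
#' reference panels that cover only 7 of the 8 counted blood cell types (the
#' missing type then acts as unmodeled noise in deconvolution).
#'
#' @param profiles Markers x types matrix from [simulate_marker_profiles()]
#'   (or the `truth$marker_profiles` of a simulated cohort, so probe ids
#'   match the cohort's methylation matrix).
#' @param n_rep Replicates per cell type (default 6).
#' @param noise_sd Beta-scale replicate noise (default 0.03).
#' @param types Types to emit (default all but `"Baso"`).
#' @param seed Integer seed.
#' @return List with `beta` (markers x samples matrix) and `cell_types`
#'   (identity of each sample).
#' @export
simulate_reference_samples <- function(profiles, n_rep = 6, noise_sd = 0.03,
                                       types = setdiff(colnames(profiles), "Baso"),
                                       seed = 1L) {
  abort_if(n_rep < 2, "need >= 2 replicates per cell type")
  with_seed(seed, {
    beta <- do.call(cbind, lapply(types, function(ct) {
      matrix(rep(profiles[, ct], n_rep), ncol = n_rep) +
        matrix(rnorm(nrow(profiles) * n_rep, sd = noise_sd), ncol = n_rep)
    }))
    beta <- pmin(pmax(beta, 0.001), 0.999)
    rownames(beta) <- rownames(profiles)
    cell_types <- rep(types, each = n_rep)
    colnames(beta) <- paste0(cell_types, "_r", rep(seq_len(n_rep), length(types)))
    list(beta = beta, cell_types = cell_types)
  })
}
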