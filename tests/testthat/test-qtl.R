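hwe_dosages <- function(n, m, maf = 0.3, prefix = "s") {
  d <- matrix(rbinom(n * m, 2, maf), n, m,
              dimnames = list(paste0("i", seq_len(n)),
                              sprintf("%s%04d", prefix, seq_len(m))))
  d
}

test_that("single-SNP OLS association behaves at the extremes and under the null", {
  set.seed(401)
  n <- 400
  D <- hwe_dosages(n, 5)
  # exact linear trait: p at the floor, R2 = 1
  y <- 2 * D[, 3]
  names(y) <- rownames(D)
  scan <- single_snp_assoc(y, D)
  expect_equal(scan$p[scan$snp == "s0003"], 1e-300)
  expect_equal(scan$r2[scan$snp == "s0003"], 1, tolerance = 1e-9)

  # null p-values are uniform (unrelated individuals), three seeds
  for (s in 1:3) {
    set.seed(401 + s)
    D0 <- hwe_dosages(n, 1000)
    y0 <- rnorm(n); names(y0) <- rownames(D0)
    p <- single_snp_assoc(y0, D0)$p
    expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
  }

  # monomorphic SNPs skipped and tallied
  Dm <- D; Dm[, 2] <- 1
  expect_message(sm <- single_snp_assoc(y, Dm), "monomorphic")
  expect_false("s0002" %in% sm$snp)
  expect_equal(attr(sm, "skipped_monomorphic"), 1)

  expect_error(single_snp_assoc(y[1:10], D[1:10, ]), "30")
})

test_that("detection power matches the non-central chi-square oracle", {
  # planted SNP explaining 30% of variance at n = 400: power at p < 1e-5 is
  # essentially 1 by the non-centrality computation
  n <- 400
  r2 <- 0.30
  ncp <- n * r2 / (1 - r2)
  crit <- qchisq(1e-5, 1, lower.tail = FALSE)
  expect_gt(pchisq(crit, 1, ncp = ncp, lower.tail = FALSE), 0.999999)
  set.seed(402)
  hits <- 0
  for (k in 1:100) {
    g <- rbinom(n, 2, 0.3)
    gs <- scale(g)[, 1]
    y <- sqrt(r2) * gs + sqrt(1 - r2) * rnorm(n)
    names(y) <- paste0("i", 1:n)
    D <- matrix(g, ncol = 1, dimnames = list(names(y), "s0001"))
    hits <- hits + (single_snp_assoc(y, D)$p < 1e-5)
  }
  expect_gte(hits, 99)

  # at a moderate effect the empirical power tracks the closed form
  r2w <- 0.06
  ncp_w <- n * r2w / (1 - r2w)
  oracle <- pchisq(crit, 1, ncp = ncp_w, lower.tail = FALSE)
  set.seed(403)
  hits_w <- 0
  reps <- 400
  for (k in seq_len(reps)) {
    g <- rbinom(n, 2, 0.3)
    gs <- scale(g)[, 1]
    y <- sqrt(r2w) * gs + sqrt(1 - r2w) * rnorm(n)
    names(y) <- paste0("i", 1:n)
    D <- matrix(g, ncol = 1, dimnames = list(names(y), "s0001"))
    hits_w <- hits_w + (single_snp_assoc(y, D)$p < 1e-5)
  }
  expect_lt(abs(hits_w / reps - oracle), 0.06)
})

test_that("GLS mode deflates family-structure inflation of null statistics", {
  co <- small_cohort(seed = 404, n_families = 60, n_snps = 800)
  grm <- compute_grm(co$gen)
  # a purely polygenic trait: no single causal SNP, but high h2
  set.seed(405)
  Z <- scale(co$gen$dosage)
  g <- drop(Z %*% rnorm(ncol(Z))) ; g <- g / sd(g) * sqrt(0.6)
  y <- g + rnorm(nrow(Z), sd = sqrt(0.4))
  names(y) <- rownames(Z)
  ols <- single_snp_assoc(y, co$gen)
  gls <- single_snp_assoc(y, co$gen, grm = grm)
  lambda <- function(p) median(qchisq(p, 1, lower.tail = FALSE)) / qchisq(0.5, 1)
  expect_lt(lambda(gls$p), lambda(ols$p))
  expect_lt(abs(lambda(gls$p) - 1), 0.2)
})

test_that("shared-QTL sets match a brute-force intersection and are symmetric", {
  co <- small_cohort(seed = 406, n_families = 80, n_snps = 400)
  ts <- truth_spec(n_expr = 20, n_meth = 40, n_cell_expr = 0, n_cell_meth = 0,
                   n_shared_pairs = 5, n_latent_expr = 0, n_latent_meth = 0)
  tr <- simulate_trait_matrices(co$gen, co$props, ts, seed = 407)
  mm <- beta_to_m(tr$meth$values)

  for (i in 1:5) {
    tp <- tr$truth$pairs[i, ]
    snp_sel <- co$gen$snps$chrom == tp$chrom
    sub <- structure(list(dosage = co$gen$dosage[, snp_sel],
                          snps = co$gen$snps[snp_sel, ]),
                     class = "genotype_matrix")
    se <- single_snp_assoc(tr$expr$values[tp$expr_probe, ], sub)
    sm <- single_snp_assoc(mm[tp$meth_probe, ], sub)
    rec <- shared_qtl(se, sm)

    # the planted causal SNP is in the shared set, and is the best SNP
    expect_true(tp$snp %in% rec$shared_snps[[1]])
    expect_true(rec$same_best_snp)
    expect_equal(rec$best_esnp, tp$snp)

    # brute-force double loop over records gives the same shared set
    brute <- character()
    for (a in seq_len(nrow(se))) for (b in seq_len(nrow(sm))) {
      if (se$snp[a] == sm$snp[b] && se$p[a] < 1e-5 && sm$p[b] < 1e-5) {
        brute <- c(brute, se$snp[a])
      }
    }
    expect_setequal(rec$shared_snps[[1]], brute)

    # role symmetry
    swap <- shared_qtl(sm, se)
    expect_setequal(swap$shared_snps[[1]], rec$shared_snps[[1]])
    expect_equal(swap$best_esnp, rec$best_msnp)
    expect_equal(swap$best_distance, rec$best_distance)
  }

  # disjoint strong causal SNPs on the same chromosome, no LD -> empty set
  set.seed(408)
  n <- 500
  D <- hwe_dosages(n, 50)
  ann <- tibble::tibble(snp = colnames(D), chrom = "1",
                        pos = seq(1e6, 50e6, length.out = 50))
  gm <- structure(list(dosage = D, snps = ann), class = "genotype_matrix")
  y1 <- 2 * D[, 5] + rnorm(n); names(y1) <- rownames(D)
  y2 <- 2 * D[, 40] + rnorm(n); names(y2) <- rownames(D)
  rec0 <- shared_qtl(single_snp_assoc(y1, gm), single_snp_assoc(y2, gm))
  expect_equal(rec0$n_shared, 0)
  expect_false(rec0$same_best_snp)
  expect_equal(rec0$best_distance, abs(ann$pos[5] - ann$pos[40]))

  # no SNP under the relaxed cutoff -> null best SNP and distance
  y3 <- rnorm(n); names(y3) <- rownames(D)
  s3 <- single_snp_assoc(y3, gm)
  s3$p[] <- 0.99
  rec3 <- shared_qtl(s3, s3)
  expect_true(is.na(rec3$best_esnp))
  expect_true(is.na(rec3$best_distance))
})

test_that("variance explained follows the R^2 sampling expectations", {
  set.seed(409)
  g <- rbinom(500, 2, 0.4)
  expect_equal(variance_explained(g, g), 1)

  # null expectation E[R^2] ~ 1/(n-1)
  r2s <- replicate(300, variance_explained(rnorm(500), rbinom(500, 2, 0.4)))
  expect_lt(abs(mean(r2s) - 1 / 499), 1.5 / 499)

  # planted 40%-variance QTL at n = 400
  set.seed(410)
  r2p <- replicate(50, {
    g <- scale(rbinom(400, 2, 0.3))[, 1]
    y <- sqrt(0.4) * g + sqrt(0.6) * rnorm(400)
    variance_explained(y, g)
  })
  expect_lt(abs(mean(r2p) - 0.4), 0.07)
})

test_that("region merging matches a brute-force oracle and summaries tally", {
  # trivial within-window fractions
  rec <- tibble::tibble(
    expr_probe = paste0("e", 1:4), meth_probe = paste0("m", 1:4),
    n_shared = c(2L, 1L, 0L, 0L),
    distance = c(1e4, 1e4, 5e6, 5e6),
    best_distance = c(0, 2e4, 8e6, NA),
    same_best_snp = c(TRUE, FALSE, FALSE, NA),
    chrom = "1", start = c(1e6, 1.2e6, 9e6, 2e7), end = c(1.1e6, 1.3e6, 9.1e6, 2.1e7),
    r = c(0.5, -0.4, 0.3, 0.2)
  )
  s <- summarize_shared_qtl(rec, window = 1e6, merge_dist = 1e6)
  expect_equal(s$n_pairs, 4L)
  expect_equal(s$n_sharing, 2L)
  expect_equal(unname(s$frac_within_window), c(1, 0))
  expect_equal(s$n_same_best_snp, 1L)
  expect_equal(s$n_regions, 1L)  # the two sharing pairs merge
  expect_equal(unname(s$mean_abs_r), c(0.45, 0.25))

  # empty input
  expect_equal(summarize_shared_qtl(rec[0, ])$n_pairs, 0L)

  # interval merging equals a brute-force transitive-closure oracle
  set.seed(411)
  for (k in 1:20) {
    m <- sample(2:25, 1)
    st <- sort(sample.int(5e7, m))
    en <- st + sample.int(2e5, m)
    gap <- 1e6
    got <- nrow(merge_genomic_regions(rep("1", m), st, en, gap = gap))
    # brute force: union-find over all overlapping-within-gap interval pairs
    lab <- seq_len(m)
    repeat {
      changed <- FALSE
      for (a in 1:m) for (b in 1:m) {
        if (st[b] <= en[a] + gap && st[a] <= en[b] + gap &&
            lab[b] != lab[a]) {
          lab[lab == max(lab[a], lab[b])] <- min(lab[a], lab[b])
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    expect_equal(got, length(unique(lab)))
  }
})
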