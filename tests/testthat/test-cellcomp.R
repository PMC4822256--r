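test_that("observed proportions are count ratios", {
  counts <- rbind(a = c(5, 5, 0, 0, 0, 0, 0, 0),
                  b = rep(10, 8),
                  c = rep(0, 8))
  colnames(counts) <- names(blood_base_profile())
  expect_warning(op <- observed_proportions(counts), "zero total")
  expect_equal(unname(op$props["a", 1:2]), c(0.5, 0.5))
  expect_equal(unname(op$props["b", ]), rep(1 / 8, 8))
  expect_true(all(is.na(op$props["c", ])))

  set.seed(301)
  rnd <- matrix(rpois(80, 50), 10, 8,
                dimnames = list(paste0("i", 1:10), colnames(counts)))
  expect_lt(max(abs(rowSums(observed_proportions(rnd)$props) - 1)), 1e-12)
  expect_error(observed_proportions(-rnd), "non-negative")
})

test_that("moderated one-vs-rest t ranks markers correctly", {
  set.seed(302)
  types <- rep(c("A", "B", "C"), each = 4)
  n_probe <- 50
  beta <- matrix(runif(n_probe * 12, 0.3, 0.7), n_probe, 12,
                 dimnames = list(sprintf("p%02d", 1:n_probe), NULL))
  # probe p01: 0.9 in A, 0.1 elsewhere, tiny variance -> rank 1 for A
  beta[1, ] <- ifelse(types == "A", 0.9, 0.1) + rnorm(12, sd = 1e-4)
  ranks <- rank_celltype_markers(beta, types)
  expect_equal(ranks$probe[ranks$cell_type == "A" & ranks$rank == 1], "p01")

  # constant probe ranks last
  beta2 <- beta
  beta2[2, ] <- 0.5
  r2 <- rank_celltype_markers(beta2, types)
  expect_true(all(r2$rank[r2$probe == "p02"] == n_probe))
  expect_true(all(r2$t[r2$probe == "p02"] == 0))

  # equal within-group variances across probes: shrinkage is a no-op,
  # moderated ranking equals the plain pooled-t ranking
  base <- rnorm(12, sd = 0.05)
  beta3 <- t(sapply(1:20, function(i) {
    mu <- runif(3)
    mu[match(types, c("A", "B", "C"))] + base
  }))
  rownames(beta3) <- sprintf("q%02d", 1:20)
  rm_ <- rank_celltype_markers(beta3, types, prior_n = 4)
  rp <- rank_celltype_markers(beta3, types, prior_n = 0)
  expect_equal(rm_$rank, rp$rank)

  # independent cross-check: limma's one-vs-rest moderated t gives the same
  # ordering of clearly differential probes
  set.seed(303)
  sig <- t(sapply(1:30, function(i) {
    d <- runif(1, 0.1, 0.6)
    ifelse(types == "A", 0.5 + d / 2, 0.5 - d / 2) + rnorm(12, sd = 0.03)
  }))
  rownames(sig) <- sprintf("s%02d", 1:30)
  ours <- rank_celltype_markers(sig, types)
  ours_a <- ours[ours$cell_type == "A", ]
  design <- cbind(Intercept = 1, A = as.numeric(types == "A"))
  lf <- limma::eBayes(limma::lmFit(sig, design))
  limma_rank <- rank(-abs(lf$t[, "A"]))
  # the two variance priors differ, so orderings agree closely but not exactly
  expect_gt(cor(ours_a$rank[match(rownames(sig), ours_a$probe)], limma_rank,
                method = "spearman"), 0.9)
})

test_that("reference construction takes the top-k union and honors availability", {
  set.seed(304)
  types <- rep(c("A", "B", "C"), each = 3)
  beta <- matrix(runif(30 * 9), 30, 9,
                 dimnames = list(sprintf("p%02d", 1:30), NULL))
  beta[1, ] <- ifelse(types == "A", 0.9, 0.1)
  beta[2, ] <- ifelse(types == "B", 0.85, 0.15)
  beta[3, ] <- ifelse(types == "C", 0.8, 0.1)
  ranks <- rank_celltype_markers(beta, types)

  # k = 1 with disjoint top markers -> 3 probes
  ref1 <- build_reference_matrix(ranks, beta, types, k_per_type = 1)
  expect_equal(sort(rownames(ref1$profile)), c("p01", "p02", "p03"))

  # union matches brute force and is bounded by k * n_types
  k <- 7
  refk <- build_reference_matrix(ranks, beta, types, k_per_type = k)
  brute <- unique(unlist(lapply(unique(types), function(ct) {
    rr <- ranks[ranks$cell_type == ct, ]
    rr$probe[order(rr$rank)][1:k]
  })))
  expect_setequal(rownames(refk$profile), brute)
  expect_lte(nrow(refk$profile), k * 3)

  # availability mask drops missing probes with a message
  avail <- setdiff(rownames(refk$profile), c("p01", "p02"))
  expect_message(refa <- build_reference_matrix(ranks, beta, types,
                                                k_per_type = k,
                                                available = avail),
                 "absent")
  expect_equal(nrow(refa$profile), nrow(refk$profile) - 2)

  # probe-order permutation leaves the selection unchanged
  perm <- sample(nrow(beta))
  ranks_p <- rank_celltype_markers(beta[perm, ], types)
  refp <- build_reference_matrix(ranks_p, beta[perm, ], types, k_per_type = k)
  expect_setequal(rownames(refp$profile), rownames(refk$profile))
})

test_that("deconvolution is exact on noiseless mixtures and accurate with noise", {
  prof <- simulate_marker_profiles(210, seed = 305)
  types7 <- setdiff(colnames(prof), "Baso")
  ref <- simulate_reference_samples(prof, seed = 306)
  ranks <- rank_celltype_markers(ref$beta, ref$cell_types)
  rm7 <- build_reference_matrix(ranks, ref$beta, ref$cell_types, k_per_type = 30)
  R <- rm7$profile

  # a sample equal to one reference column -> unit coefficient vector
  one <- matrix(R[, "CD4T"], ncol = 1, dimnames = list(rownames(R), "s1"))
  p1 <- predict_proportions(one, rm7)
  expect_equal(unname(p1$props["s1", ]),
               as.numeric(colnames(R) == "CD4T"), tolerance = 1e-10)

  # exact mixture 0.3 A + 0.7 B recovered to 1e-10
  mix <- matrix(0.3 * R[, 1] + 0.7 * R[, 2], ncol = 1,
                dimnames = list(rownames(R), "s2"))
  p2 <- predict_proportions(mix, rm7)
  want <- numeric(ncol(R)); want[1:2] <- c(0.3, 0.7)
  expect_equal(unname(p2$props["s2", ]), want, tolerance = 1e-10)

  # Dirichlet mixtures + noise sd 0.02: per-type correlation > 0.9
  set.seed(307)
  n <- 200
  true_p <- emcovar:::rdirichlet(n, 40 * blood_base_profile()[types7])
  colnames(true_p) <- types7
  noisy <- prof[rownames(R), types7] %*% t(true_p) +
    matrix(rnorm(nrow(R) * n, sd = 0.02), nrow(R))
  colnames(noisy) <- paste0("i", 1:n)
  pn <- predict_proportions(noisy, rm7)
  for (ct in types7) {
    expect_gt(cor(pn$props[, ct], true_p[, ct]), 0.9)
  }

  # rank-deficient reference errors out naming the collinear types
  bad <- rm7
  bad$profile[, "NK"] <- bad$profile[, "Mono"]
  expect_error(predict_proportions(noisy, bad), "collinear")
})

test_that("calibration enforces slope one and intercept zero", {
  set.seed(308)
  obs <- emcovar:::new_cell_props(
    matrix(runif(60, 0.1, 0.3), 20, 3,
           dimnames = list(paste0("i", 1:20), c("A", "B", "C"))), "observed")
  # predictions equal to observed -> identity map
  same <- emcovar:::new_cell_props(obs$props, "predicted-raw")
  cal0 <- calibrate_predictions(same, obs)
  expect_equal(cal0$props, obs$props, tolerance = 1e-12)
  expect_equal(cal0$calibration$slope, rep(1, 3), tolerance = 1e-10)

  # predicted = 2 * observed + 0.1 -> map recovered; post-fit slope 1, int 0
  shifted <- emcovar:::new_cell_props(2 * obs$props + 0.1, "predicted-raw")
  cal <- calibrate_predictions(shifted, obs)
  expect_equal(cal$calibration$slope, rep(2, 3), tolerance = 1e-10)
  expect_equal(cal$calibration$intercept, rep(0.1, 3), tolerance = 1e-10)
  for (ct in c("A", "B", "C")) {
    f <- lm(cal$props[, ct] ~ obs$props[, ct])
    expect_equal(unname(coef(f)), c(0, 1), tolerance = 1e-10)
    # affine map preserves rank correlation
    expect_equal(cor(cal$props[, ct], obs$props[, ct], method = "spearman"),
                 cor(shifted$props[, ct], obs$props[, ct], method = "spearman"))
  }

  # zero-variance prediction is passed through with a warning
  flat <- emcovar:::new_cell_props(
    cbind(A = rep(0.2, 20), obs$props[, 2:3]), "predicted-raw")
  expect_warning(calibrate_predictions(flat, obs), "zero-variance")
})

test_that("adjustment residualizes traits on proportions", {
  co <- small_cohort(seed = 309, n_families = 30)
  P <- co$props$props
  n <- nrow(P)
  ids <- rownames(P)

  # trait proportional to neutrophil fraction: residual uncorrelated with it
  set.seed(310)
  tr <- rbind(t1 = 3 * P[, "Neu"] + rnorm(n, sd = 0.1),
              t2 = rnorm(n))
  colnames(tr) <- ids
  expect_warning(adj <- adjust_for_proportions(tr, co$props), "collinear")
  expect_lt(abs(cor(adj["t1", ], P[, "Neu"])), 1e-10)

  # already-orthogonal traits pass through; idempotence
  suppressWarnings({
    adj2 <- adjust_for_proportions(adj, co$props)
  })
  expect_equal(adj2, adj, tolerance = 1e-10)

  # missing values: residuals computed on the observed subset per probe
  tr_na <- tr
  tr_na[1, 1:5] <- NA
  suppressWarnings(adj_na <- adjust_for_proportions(tr_na, co$props))
  expect_true(all(is.na(adj_na[1, 1:5])))
  ok <- !is.na(adj_na[1, ])
  expect_lt(abs(cor(adj_na[1, ok], P[ok, "Neu"])), 1e-10)
})

test_that("residual confounding closed form matches direct simulation", {
  expect_equal(residual_confounding_fraction(1), 0)
  expect_equal(residual_confounding_fraction(0.75), 0.4375)
  expect_equal(residual_confounding_fraction(0.95), 0.0975)
  for (rp in c(0.5, 0.75, 0.9, 0.95)) {
    sim <- simulate_residual_confounding(rp, n = 1e5, n_pairs = 25, seed = 311)
    expect_lt(abs(sim - residual_confounding_fraction(rp)), 0.01)
  }
})

test_that("beta/M transform is the logit2 with a clean inverse", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  grid <- seq(0.01, 0.99, by = 0.01)
  expect_equal(m_to_beta(beta_to_m(grid)), grid, tolerance = 1e-12)
  expect_true(all(diff(beta_to_m(grid)) > 0))
  expect_error(beta_to_m(1.1), "beta")
  expect_error(beta_to_m(-0.2), "beta")
  # clipping keeps extreme betas finite
  expect_true(is.finite(beta_to_m(0)) && is.finite(beta_to_m(1)))
})
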