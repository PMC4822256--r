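test_that("pedigree structure follows the family design", {
  # one family forced to 2 parents + MZ pair, no extra sibs
  ped <- simulate_pedigree(1, family_spec = list(p_mz = 1, sib_probs = 1),
                           seed = 7)
  expect_equal(nrow(ped), 4)
  expect_equal(sum(ped$role == "parent"), 2)
  expect_equal(sum(ped$role == "mz"), 2)
  mz <- ped[ped$role == "mz", ]
  expect_equal(mz$father[1], mz$father[2])
  expect_equal(mz$mother[1], mz$mother[2])
  expect_equal(mz$mz_group[1], mz$mz_group[2])
  expect_equal(mz$sex[1], mz$sex[2])

  # parents precede offspring and no one is their own ancestor
  ped2 <- simulate_pedigree(20, seed = 3)
  idx <- setNames(seq_len(nrow(ped2)), ped2$id)
  kids <- !is.na(ped2$father)
  expect_true(all(idx[ped2$father[kids]] < which(kids)))
  expect_true(all(idx[ped2$mother[kids]] < which(kids)))

  # the default composition gives ~610 individuals for 117 families
  sizes <- vapply(1:3, function(s) nrow(simulate_pedigree(117, seed = s)),
                  numeric(1))
  expect_true(all(sizes > 540 & sizes < 680))

  # determinism and input validation
  expect_identical(simulate_pedigree(5, seed = 11),
                   simulate_pedigree(5, seed = 11))
  expect_error(simulate_pedigree(0), "n_families")
  expect_error(simulate_pedigree(2, family_spec = list(sib_probs = c(-1, 2))),
               "sib_probs")
})

test_that("gene-dropped genotypes are Mendelian, HWE at founders, identical for MZ", {
  co <- small_cohort()
  expect_equal(check_mendelian(co$gen, co$ped), 0)

  mzg <- co$ped$mz_group
  for (g in unique(mzg[!is.na(mzg)])) {
    rows <- co$gen$dosage[co$ped$id[which(mzg == g)], ]
    expect_identical(rows[1, ], rows[2, ])
  }

  # founder allele frequency at fixed MAF 0.3 with 1,000 founders
  ped <- simulate_pedigree(500, family_spec = list(sib_probs = 1), seed = 5)
  founders <- ped$id[ped$role == "parent"]
  gen <- simulate_genotypes(ped, 300, maf_range = c(0.3, 0.3), seed = 6)
  freq <- colMeans(gen$dosage[founders, ]) / 2
  expect_lt(max(abs(mean(freq) - 0.3)), 0.005)
  expect_lt(max(abs(freq - 0.3)), 0.08)

  expect_error(simulate_genotypes(co$ped, 0), "n_snps")
  expect_error(simulate_genotypes(co$ped, 10, maf_range = c(0, 0.6)))
})

test_that("realized relatedness matches pedigree expectation", {
  ped <- simulate_pedigree(60, seed = 8)
  gen <- simulate_genotypes(ped, 2000, seed = 9)
  grm <- compute_grm(gen)
  idx <- setNames(seq_len(nrow(ped)), ped$id)
  kids <- which(!is.na(ped$father))
  po <- vapply(kids, function(i) grm$A[i, idx[[ped$father[i]]]], numeric(1))
  expect_gt(length(po), 50)
  expect_lt(abs(mean(po) - 0.5), 0.05)
})

test_that("cell proportions are Dirichlet with the declared concentration", {
  co <- small_cohort()
  p <- co$props$props
  expect_lt(max(abs(rowSums(p) - 1)), 1e-12)
  expect_true(all(p >= 0))

  # concentration -> infinity collapses to the base profile
  ped <- simulate_pedigree(10, seed = 2)
  tight <- simulate_cell_proportions(ped, concentration = 1e8, seed = 3)
  expect_lt(max(abs(sweep(tight$props, 2, blood_base_profile()))), 1e-3)

  # empirical variance tracks the Dirichlet formula p(1-p)/(c+1)
  ped_big <- simulate_pedigree(400, seed = 4)
  for (conc in c(20, 80)) {
    pr <- simulate_cell_proportions(ped_big, concentration = conc, seed = 5)
    base <- blood_base_profile()
    expected <- base * (1 - base) / (conc + 1)
    ratio <- apply(pr$props, 2, var) / expected
    expect_true(all(ratio > 0.75 & ratio < 1.3))
  }
  v20 <- apply(simulate_cell_proportions(ped_big, 20, seed = 6)$props, 2, var)
  v80 <- apply(simulate_cell_proportions(ped_big, 80, seed = 6)$props, 2, var)
  expect_true(all(v80 < v20))

  expect_error(simulate_cell_proportions(ped, concentration = 0), "concentration")
})

test_that("trait matrices realize the declared variance structure", {
  co <- small_cohort(seed = 21, n_families = 117, n_snps = 800)
  ts <- truth_spec(n_expr = 60, n_meth = 250, n_cell_expr = 20,
                   n_cell_meth = 40, n_shared_pairs = 8,
                   n_latent_expr = 4, n_latent_meth = 8)
  tr <- simulate_trait_matrices(co$gen, co$props, ts, co$profiles, seed = 22)

  # methylation emitted strictly inside (0,1)
  expect_true(all(tr$meth$values > 0 & tr$meth$values < 1))

  # realized h2 (R^2 of trait on true genetic value) within 0.1 of target
  gv <- tr$truth$genetic_values$expr
  for (i in seq_len(nrow(gv))) {
    y <- tr$expr$values[rownames(gv)[i], ]
    expect_lt(abs(summary(lm(y ~ gv[i, ]))$r.squared - ts$shared_h2), 0.1)
  }
  # same on the M scale for methylation
  gm <- tr$truth$genetic_values$meth
  mm <- beta_to_m(tr$meth$values)
  for (i in seq_len(nrow(gm))) {
    y <- mm[rownames(gm)[i], ]
    expect_lt(abs(summary(lm(y ~ gm[i, ]))$r.squared - ts$shared_h2), 0.1)
  }

  # probes on the same cell type correlate with the product of their signs
  # before adjustment and fall to the null band after adjusting on truth
  cells <- tr$truth$probes[tr$truth$probes$class == "cell" &
                             tr$truth$probes$kind == "expression", ]
  tt <- table(cells$cell_type)
  ct <- names(tt)[which.max(tt)]
  same <- cells[cells$cell_type == ct, ]
  expect_gt(nrow(same), 1)
  v <- tr$expr$values[same$probe, ]
  expect_warning(adj <- adjust_for_proportions(tr$expr, co$props),
                 "collinear")
  va <- adj$values[same$probe, ]
  for (i in 2:nrow(same)) {
    r_pre <- cor(v[1, ], v[i, ])
    expect_gt(r_pre * same$cell_sign[1] * same$cell_sign[i], 0.3)
    expect_lt(abs(cor(va[1, ], va[i, ])), 0.25)
  }

  # a null probe is pure noise: no association with proportions or genetics
  nulls <- tr$truth$probes[tr$truth$probes$class == "null" &
                             tr$truth$probes$kind == "expression", ]
  y0 <- tr$expr$values[nulls$probe[1], ]
  expect_lt(summary(lm(y0 ~ co$props$props[, -8]))$r.squared, 0.06)

  # determinism
  tr2 <- simulate_trait_matrices(co$gen, co$props, ts, co$profiles, seed = 22)
  expect_identical(tr$expr$values, tr2$expr$values)
  expect_identical(tr$meth$values, tr2$meth$values)
})

test_that("truth spec validates its composition", {
  expect_error(truth_spec(n_expr = 10, n_cell_expr = 20), "exceed")
  expect_error(truth_spec(shared_qtl_var = 0.7, shared_h2 = 0.6), "exceed")
  expect_error(truth_spec(cell_var = 1.2), "cell_var")
})

test_that("synthetic outputs round-trip through the text writers", {
  co <- small_cohort(seed = 31, n_families = 5, n_snps = 40, n_markers = 16)
  ts <- truth_spec(n_expr = 10, n_meth = 30, n_cell_expr = 3, n_cell_meth = 5,
                   n_shared_pairs = 2, n_latent_expr = 1, n_latent_meth = 2)
  tr <- simulate_trait_matrices(co$gen, co$props, ts, co$profiles, seed = 32)
  td <- withr::local_tempdir()

  p1 <- write_trait_tsv(tr$expr, file.path(td, "expr.tsv.gz"))
  back <- read_trait_tsv(p1, kind = "expression")
  expect_equal(back$values, tr$expr$values, tolerance = 1e-12)

  write_probe_bed(tr$meth$annot, file.path(td, "meth.bed"))
  bed <- read.delim(file.path(td, "meth.bed"), header = FALSE)
  expect_equal(bed$V2, tr$meth$annot$start - 1)
  expect_equal(bed$V3, tr$meth$annot$end)

  write_pedigree_fam(co$ped, file.path(td, "ped.fam"))
  fam <- read.delim(file.path(td, "ped.fam"), header = FALSE)
  expect_equal(nrow(fam), nrow(co$ped))

  write_dosage_tsv(co$gen, file.path(td, "dose.tsv.gz"))
  dd <- read.delim(file.path(td, "dose.tsv.gz"), check.names = FALSE)
  expect_equal(unname(as.matrix(dd[, -(1:3)])), unname(t(co$gen$dosage)))

  write_truth_json(tr$truth, file.path(td, "truth.json"))
  tj <- jsonlite::read_json(file.path(td, "truth.json"), simplifyVector = TRUE)
  expect_equal(nrow(tj$probes), nrow(tr$truth$probes))
  expect_equal(tj$pairs$snp, tr$truth$pairs$snp)
})
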