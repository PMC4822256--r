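# Shared small fixtures, rebuilt per test file (cheap by construction).

# A small twin cohort with genotypes, proportions and marker profiles.
small_cohort <- function(seed = 42, n_families = 40, n_snps = 600,
                         n_markers = 120) {
  ped <- simulate_pedigree(n_families, seed = seed)
  gen <- simulate_genotypes(ped, n_snps, seed = seed + 1)
  props <- simulate_cell_proportions(ped, seed = seed + 2)
  profiles <- simulate_marker_profiles(n_markers, seed = seed + 3)
  list(ped = ped, gen = gen, props = props, profiles = profiles)
}

# Dense pairwise-complete correlation oracle for cross_correlate().
dense_cor_oracle <- function(X, Y, min_n = 10) {
  out <- list()
  for (i in seq_len(nrow(X))) for (j in seq_len(nrow(Y))) {
    ok <- !is.na(X[i, ]) & !is.na(Y[j, ])
    n <- sum(ok)
    if (n < max(min_n, 4)) next
    if (sd(X[i, ok]) == 0 || sd(Y[j, ok]) == 0) next
    r <- cor(X[i, ok], Y[j, ok])
    out[[length(out) + 1]] <- data.frame(
      expr_probe = rownames(X)[i], meth_probe = rownames(Y)[j],
      r = r, n = n, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

# Breadth-first-search component labelling oracle over an edge list.
bfs_components <- function(edges) {
  nodes <- unique(c(edges[[1]], edges[[2]]))
  adj <- split(c(edges[[2]], edges[[1]]), c(edges[[1]], edges[[2]]))
  comp <- setNames(rep(NA_integer_, length(nodes)), nodes)
  k <- 0L
  for (s in nodes) {
    if (!is.na(comp[[s]])) next
    k <- k + 1L
    queue <- s
    comp[[s]] <- k
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.na(comp[[w]])) {
          comp[[w]] <- k
          queue <- c(queue, w)
        }
      }
    }
  }
  comp
}

# Compare two component labellings as partitions (label-invariant).
same_partition <- function(a, b) {
  a <- a[sort(names(a))]; b <- b[sort(names(b))]
  identical(unname(ave(seq_along(a), a, FUN = min)),
            unname(ave(seq_along(b), b, FUN = min)))
}

# Upper normal tail by adaptive quadrature: an oracle independent of pnorm.
tail_by_quadrature <- function(z) {
  stats::integrate(stats::dnorm, z, Inf, rel.tol = 1e-12,
                   abs.tol = 0)$value
}

# polygenic trait with target h2 built from a dosage matrix
polygenic_trait <- function(dosage, h2) {
  Z <- scale(dosage)
  g <- drop(Z %*% rnorm(ncol(Z)))
  g <- g / sd(g) * sqrt(h2)
  y <- g + rnorm(nrow(Z), sd = sqrt(1 - h2))
  names(y) <- rownames(dosage)
  list(y = y, g = g)
}

# two traits with a planted genetic correlation rg and equal h2
correlated_pair <- function(dosage, rg, h2 = 0.5) {
  Z <- scale(dosage)
  m <- ncol(Z)
  u_shared <- rnorm(m); u1 <- rnorm(m); u2 <- rnorm(m)
  g1 <- drop(Z %*% (sqrt(abs(rg)) * u_shared + sqrt(1 - abs(rg)) * u1))
  g2 <- drop(Z %*% (sign(rg) * sqrt(abs(rg)) * u_shared +
                      sqrt(1 - abs(rg)) * u2))
  y1 <- g1 / sd(g1) * sqrt(h2) + rnorm(nrow(Z), sd = sqrt(1 - h2))
  y2 <- g2 / sd(g2) * sqrt(h2) + rnorm(nrow(Z), sd = sqrt(1 - h2))
  names(y1) <- names(y2) <- rownames(Z)
  list(y1 = y1, y2 = y2)
}
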