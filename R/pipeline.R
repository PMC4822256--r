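#' Configuration for the end-to-end synthetic analysis
#'
#' Collects every tunable of [run_pipeline()] with defaults matching the
#' analysis the package implements: Bonferroni control at alpha = 0.05 over
#' all expression x methylation tests, a |r| >= 0.5 graph cut, 0.5 Mb
#' cis window, 1e-5 / 1e-1 stringent/relaxed QTL cutoffs, 1 Mb sharing
#' window and top-70 markers per cell type. The default cohort is 117
#' twin families (~610 individuals), 2,000 SNPs, 2,000 expression and
#' 5,000 methylation probes.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param n_families,n_snps,maf_range,chrom_layout,concentration Cohort
#'   generator settings (see the `simulate_*` functions).
#' @param truth A [truth_spec()].
#' @param n_markers Cell-type marker probes embedded in the methylation
#'   matrix (and available as a purified-cell reference).
#' @param alpha,min_n,block Correlation-stage settings.
#' @param r_cut_graph Graph edge threshold on |r|.
#' @param cis_window,share_window,merge_dist Distance windows in bp.
#' @param stringent_p,relaxed_p Shared-QTL cutoffs.
#' @param k_per_type Marker rank cutoff for the deconvolution reference.
#' @param adjust_on `"observed"`, `"predicted"` or `"none"`.
#' @param observed_subset `"children"` (cell counts available only for twins
#'   and siblings, mirroring cohorts where parents lack counts) or `"all"`.
#' @param max_rg_pairs Cap on bivariate REML fits in the rG stage.
#' @param maf_floor GRM MAF filter.
#' @param out_dir Optional directory for stage checkpoints; a rerun with the
#'   same config resumes from them.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            n_families = 117, n_snps = 2000,
                            maf_range = c(0.05, 0.5),
                            chrom_layout = c(`1` = 2e8, `2` = 2e8),
                            concentration = 40,
                            truth = truth_spec(),
                            n_markers = 300,
                            alpha = 0.05, min_n = 10, block = c(1000L, 2000L),
                            r_cut_graph = 0.5,
                            cis_window = 5e5, share_window = 1e6,
                            merge_dist = 1e6,
                            stringent_p = 1e-5, relaxed_p = 0.1,
                            k_per_type = 70,
                            adjust_on = c("observed", "predicted", "none"),
                            observed_subset = c("children", "all"),
                            max_rg_pairs = 100,
                            maf_floor = 0.01,
                            out_dir = NULL) {
  cfg <- as.list(environment())
  cfg$adjust_on <- match.arg(adjust_on)
  cfg$observed_subset <- match.arg(observed_subset)
  structure(cfg, class = "pipeline_config")
}

#' Hash of the semantically meaningful configuration fields
#'
#' @param config A `pipeline_config`.
#' @return Character hash; identical iff every field other than `out_dir`
#'   is identical.
#' @export
config_hash <- function(config) {
  rlang::hash(config[setdiff(names(config), "out_dir")])
}

#' Run the full synthetic analysis pipeline
#'
#' Stages, in order: simulate cohort -> exhaustive correlation with
#' Bonferroni control -> correlation-graph confounding diagnostic -> cell
#' proportion adjustment (observed or predicted) -> re-correlation ->
#' shared-QTL analysis of same-chromosome pairs -> bivariate REML genetic
#' correlations. Stage outputs are checkpointed to `config$out_dir` when
#' given; a failed run resumes from the last completed stage.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report`: counts per stage (including the pre/post
#'   adjustment fold reduction), graph component summaries, shared-QTL
#'   summary, stratified genetic-correlation summary, and the underlying
#'   tables.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  hash <- config_hash(cfg)
  stage <- function(name, expr) {
    if (!is.null(cfg$out_dir)) {
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      f <- file.path(cfg$out_dir, paste0(name, "-", hash, ".rds"))
      if (file.exists(f)) return(readRDS(f))
      val <- force(expr)
      saveRDS(val, f)
      return(val)
    }
    force(expr)
  }
  base <- as.integer(cfg$seed)

  sim <- stage("simulate", {
    ped <- simulate_pedigree(cfg$n_families, seed = base + 1L)
    gen <- simulate_genotypes(ped, cfg$n_snps, cfg$maf_range,
                              cfg$chrom_layout, seed = base + 2L)
    props <- simulate_cell_proportions(ped, cfg$concentration,
                                       seed = base + 3L)
    profiles <- simulate_marker_profiles(cfg$n_markers, seed = base + 4L)
    traits <- simulate_trait_matrices(gen, props, cfg$truth, profiles,
                                      seed = base + 5L)
    list(ped = ped, gen = gen, props = props, traits = traits)
  })
  expr <- sim$traits$expr
  meth_beta <- sim$traits$meth
  meth_m <- new_trait_matrix(beta_to_m(meth_beta$values), meth_beta$annot,
                             "methylation_m")
  n_tests <- nrow(expr$values) * nrow(meth_m$values)
  p_cut <- bonferroni_threshold(n_tests, cfg$alpha)

  pre <- stage("correlate_pre", {
    pairs <- cross_correlate(expr, meth_m, block = cfg$block,
                             p_cut = p_cut, min_n = cfg$min_n)
    pair_distance_and_class(pairs, expr$annot, meth_beta$annot,
                            cis_window = cfg$cis_window)
  })
  graph_pre <- build_correlation_graph(pre, cfg$r_cut_graph)
  sum_pre <- component_summary(graph_pre)

  adj <- stage("adjust", {
    if (cfg$adjust_on == "none") {
      list(expr = expr, meth = meth_m, n_used = ncol(expr$values),
           proportions = NULL)
    } else {
      subset_ids <- if (cfg$observed_subset == "children") {
        sim$ped$id[sim$ped$role != "parent"]
      } else {
        sim$ped$id
      }
      totals <- with_seed(base + 6L,
        sample(4000:9000, length(subset_ids), replace = TRUE))
      counts <- round(sim$props$props[subset_ids, , drop = FALSE] * totals)
      obs <- observed_proportions(counts)
      use_props <- if (cfg$adjust_on == "observed") {
        obs
      } else {
        ref <- simulate_reference_samples(sim$traits$truth$marker_profiles,
                                          seed = base + 7L)
        ranks <- rank_celltype_markers(ref$beta, ref$cell_types)
        refmat <- build_reference_matrix(ranks, ref$beta, ref$cell_types,
                                         k_per_type = cfg$k_per_type,
                                         available = rownames(meth_beta$values))
        pred <- predict_proportions(meth_beta, refmat)
        calibrate_predictions(pred, obs)
      }
      list(expr = adjust_for_proportions(expr, use_props),
           meth = adjust_for_proportions(meth_m, use_props),
           n_used = sum(rownames(use_props$props) %in% colnames(expr$values)),
           proportions = use_props)
    }
  })

  post <- stage("correlate_post", {
    pairs <- cross_correlate(adj$expr, adj$meth, block = cfg$block,
                             p_cut = p_cut, min_n = cfg$min_n)
    pair_distance_and_class(pairs, expr$annot, meth_beta$annot,
                            cis_window = cfg$cis_window)
  })
  graph_post <- build_correlation_graph(post, cfg$r_cut_graph)
  sum_post <- component_summary(graph_post)

  qtl <- stage("qtl", {
    sc <- filter(post, .data$same_chromosome)
    scans <- list()
    scan_for <- function(probe, trait_mat, chrom_p) {
      key <- paste(probe, chrom_p)
      if (is.null(scans[[key]])) {
        snp_set <- sim$gen$snps$snp[sim$gen$snps$chrom == chrom_p]
        sub <- list(dosage = sim$gen$dosage[, snp_set, drop = FALSE],
                    snps = sim$gen$snps[sim$gen$snps$chrom == chrom_p, ])
        class(sub) <- "genotype_matrix"
        scans[[key]] <<- single_snp_assoc(trait_mat$values[probe, ], sub)
      }
      scans[[key]]
    }
    records <- lapply(seq_len(nrow(sc)), function(i) {
      ch <- sc$chrom_e[i]
      se <- scan_for(sc$expr_probe[i], adj$expr, ch)
      sm <- scan_for(sc$meth_probe[i], adj$meth, ch)
      rec <- shared_qtl(se, sm, cfg$stringent_p, cfg$relaxed_p)
      ea <- expr$annot[expr$annot$probe == sc$expr_probe[i], ]
      ma <- meth_beta$annot[meth_beta$annot$probe == sc$meth_probe[i], ]
      best_r2 <- function(scan, snp) if (is.na(snp)) NA_real_ else
        scan$r2[match(snp, scan$snp)]
      tibble(
        expr_probe = sc$expr_probe[i], meth_probe = sc$meth_probe[i],
        r = sc$r[i], chrom = ch, distance = sc$distance[i],
        start = min(ea$start, ma$start), end = max(ea$end, ma$end),
        best_esnp_r2 = best_r2(se, rec$best_esnp),
        best_msnp_r2 = best_r2(sm, rec$best_msnp)
      ) %>% bind_cols(rec)
    })
    records <- if (length(records)) bind_rows(records) else
      tibble(expr_probe = character(), meth_probe = character(),
             r = numeric(), chrom = character(), distance = numeric(),
             start = numeric(), end = numeric(),
             best_esnp_r2 = numeric(), best_msnp_r2 = numeric(),
             n_shared = integer(), shared_snps = list(),
             best_esnp = character(), best_msnp = character(),
             best_distance = numeric(), same_best_snp = logical())
    records
  })
  share_summary <- summarize_shared_qtl(qtl, window = cfg$share_window,
                                        merge_dist = cfg$merge_dist)

  rg <- stage("rg", {
    grm <- compute_grm(sim$gen, cfg$maf_floor)
    sc <- filter(post, .data$same_chromosome)
    tr <- filter(post, !.data$same_chromosome)
    sel <- bind_rows(sc, head(tr, max(0, cfg$max_rg_pairs - nrow(sc))))
    sel <- head(sel, cfg$max_rg_pairs)
    fits <- batch_genetic_correlations(sel, adj$expr, adj$meth, grm)
    left_join(fits,
              sel[, c("expr_probe", "meth_probe", "same_chromosome")],
              by = c("expr_probe", "meth_probe")) %>%
      left_join(qtl[, c("expr_probe", "meth_probe", "n_shared")],
                by = c("expr_probe", "meth_probe")) %>%
      mutate(stratum = case_when(
        !is.na(.data$n_shared) & .data$n_shared > 0 ~ "shared_qtl",
        .data$same_chromosome ~ "same_chrom_no_shared",
        TRUE ~ "diff_chrom"
      ))
  })
  rg_summary <- rg %>%
    filter(!is.na(.data$rG)) %>%
    group_by(.data$stratum) %>%
    summarise(n = n(), mean_abs_rg = mean(abs(.data$rG)), .groups = "drop")

  structure(list(
    config = cfg, config_hash = hash,
    counts = list(
      n_individuals = nrow(sim$ped),
      n_families = cfg$n_families,
      n_expr = nrow(expr$values), n_meth = nrow(meth_m$values),
      n_tests = n_tests, bonferroni_p = p_cut,
      min_significant_r = min_significant_r(ncol(expr$values), p_cut),
      n_pairs_pre = nrow(pre), n_pairs_post = nrow(post),
      fold_reduction = nrow(pre) / max(nrow(post), 1L),
      n_adjust_individuals = adj$n_used,
      n_same_chrom_post = sum(post$same_chromosome, na.rm = TRUE)
    ),
    graph_pre = sum_pre, graph_post = sum_post,
    share_summary = share_summary,
    rg_summary = rg_summary,
    tables = list(pairs_pre = pre, pairs_post = post,
                  shared_qtl = qtl, rg = rg),
    truth = sim$traits$truth
  ), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  ct <- x$counts
  cat("<pipeline_report>\n")
  cat("  cohort: ", ct$n_individuals, " individuals, ", ct$n_expr, " x ",
      ct$n_meth, " probes (", format(ct$n_tests, big.mark = ","),
      " tests)\n", sep = "")
  cat("  Bonferroni p <= ", format(ct$bonferroni_p, digits = 3),
      " (|r| >= ", round(ct$min_significant_r, 3), " at n = ",
      ct$n_individuals, ")\n", sep = "")
  cat("  significant pairs: ", ct$n_pairs_pre, " pre-adjustment -> ",
      ct$n_pairs_post, " post (", round(ct$fold_reduction, 1),
      "-fold reduction)\n", sep = "")
  cat("  largest component: ", x$graph_pre$largest_size, " of ",
      nrow(x$graph_pre$components) , " components pre; ",
      x$graph_post$largest_size, " post\n", sep = "")
  if (!is.null(x$share_summary$n_pairs) && x$share_summary$n_pairs > 0) {
    cat("  shared QTL: ", x$share_summary$n_sharing, "/",
        x$share_summary$n_pairs, " same-chromosome pairs share >= 1 QTL\n",
        sep = "")
  }
  invisible(x)
}

#' Result tables of a pipeline run
#'
#' @param report A `pipeline_report`.
#' @return Named list of tibbles: `significant_pairs` (post-adjustment
#'   Bonferroni-passing pairs with distances and classes), `shared_qtl_pairs`
#'   (per same-chromosome pair sharing records), `best_snps` (best e/mSNP and
#'   its variance explained per pair), `genetic_correlations`, and
#'   `components` (post-adjustment graph components).
#' @export
report_tables <- function(report) {
  sq <- report$tables$shared_qtl
  list(
    significant_pairs = report$tables$pairs_post,
    shared_qtl_pairs = select(sq, -"shared_snps", -"best_esnp_r2",
                              -"best_msnp_r2"),
    best_snps = select(sq, "expr_probe", "meth_probe", "best_esnp",
                       "best_esnp_r2", "best_msnp", "best_msnp_r2",
                       "best_distance", "same_best_snp"),
    genetic_correlations = report$tables$rg,
    components = report$graph_post$components
  )
}

#' Write pipeline report tables as TSV
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory (created if needed).
#' @return Paths written, invisibly.
#' @export
write_report_tables <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- report_tables(report)
  paths <- vapply(names(tabs), function(nm) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    write.table(as.data.frame(tabs[[nm]]), p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}
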