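# Genotype ratio statistics, the congruence filter, and fold-change tests.

make_expr <- function(values_by_genotype, probes = 1) {
  # values_by_genotype: list(WT = c(...), APC = c(...), APCMYC = c(...))
  samples <- unlist(lapply(names(values_by_genotype), function(g)
    paste0(g, "_", seq_along(values_by_genotype[[g]]))))
  design <- data.frame(
    sample = samples,
    genotype = rep(names(values_by_genotype),
                   lengths(values_by_genotype)))
  vals <- unlist(values_by_genotype)
  expr <- data.frame(probe_id = paste0("p", seq_len(probes)),
                     gene_id = "g1",
                     matrix(rep(vals, each = probes), nrow = probes,
                            dimnames = list(NULL, samples)),
                     check.names = FALSE)
  list(expr = expr, design = design)
}

test_that("genotype folds are 2^(difference of log2 means)", {
  f <- make_expr(list(WT = c(5, 5, 5, 5), APC = c(5, 5, 5, 5),
                      APCMYC = c(5, 5, 5, 5)))
  r <- suppressWarnings(compute_genotype_ratios(f$expr, f$design))
  expect_equal(r$fold_APC_WT, 1.0)

  f2 <- make_expr(list(WT = c(5, 5.2, 4.8, 5), APC = c(7, 7.2, 6.8, 7),
                       APCMYC = c(5.1, 5, 5.2, 4.7)))
  r2 <- compute_genotype_ratios(f2$expr, f2$design)
  expect_equal(r2$fold_APC_WT, 4.0)  # APC mean is WT mean + 2 on log2
  expect_equal(r2$ratio_APCMYC_WT, 2^(mean(c(5.1, 5, 5.2, 4.7)) - 5))
})

test_that("Welch p-values match the textbook formula to 1e-10", {
  wt <- c(6.10, 5.85, 6.40, 6.05)
  apc <- c(7.02, 7.31, 6.88, 7.25)
  apcmyc <- c(6.20, 5.95, 6.30, 6.24)
  f <- make_expr(list(WT = wt, APC = apc, APCMYC = apcmyc))
  r <- compute_genotype_ratios(f$expr, f$design)
  expect_equal(r$p_APC_WT, oracle_welch_p(apc, wt), tolerance = 1e-10)
  expect_equal(r$p_APCMYC_APC, oracle_welch_p(apcmyc, apc),
               tolerance = 1e-10)
})

test_that("degenerate zero-variance probes report p = 1 with a flag", {
  f <- make_expr(list(WT = c(5, 5, 5), APC = c(5, 5, 5),
                      APCMYC = c(6, 6, 6)))
  expect_warning(r <- compute_genotype_ratios(f$expr, f$design),
                 "zero-variance")
  expect_true(all(r$degenerate))
  expect_equal(r$p_APC_WT, 1)
  # missing genotype is a design error
  f2 <- make_expr(list(WT = c(5, 5, 5), APC = c(6, 6, 6)))
  expect_error(compute_genotype_ratios(f2$expr, f2$design), "APCMYC")
})

test_that("the congruence filter keeps a textbook pass and drops band violations", {
  base <- data.frame(
    probe_id = paste0("p", 1:3), gene_id = "g1",
    fold_APC_WT = 2.5, p_APC_WT = 0.01,
    ratio_APCMYC_WT = 1.05, fold_APCMYC_APC = 0.4, p_APCMYC_APC = 0.01,
    degenerate = FALSE)
  prot <- data.frame(protein_id = "P_g1", gene_id = "g1",
                     fold_APC_WT = 1.3)
  kept <- apply_congruence_filter(base, prot)
  expect_equal(kept$gene_id, "g1")
  expect_equal(kept$n_passing_probes, 3L)
  expect_equal(kept$protein_fold, 1.3)

  # one of only three probes drifts outside the 0.75-1.25 band
  drift <- base
  drift$ratio_APCMYC_WT[2] <- 1.3
  expect_equal(nrow(apply_congruence_filter(drift, prot)), 0)
  # protein support below 1.2-fold also disqualifies
  weak_prot <- transform(prot, fold_APC_WT = 1.1)
  expect_equal(nrow(apply_congruence_filter(base, weak_prot)), 0)
  # empty inputs are not an error
  expect_equal(nrow(apply_congruence_filter(base[0, ], prot)), 0)
})

test_that("the filter equals the brute-force predicate on random tables", {
  for (seed in c(101, 202, 303)) {
    ratios <- random_ratio_table(200, seed = seed)
    prot <- random_protein_table(unique(ratios$gene_id)[
      seq(1, 200, by = 2)], seed = seed)
    cr <- filter_criteria()
    got <- apply_congruence_filter(ratios, prot, cr)
    expect_identical(got$gene_id, oracle_congruence(ratios, prot, cr))
  }
})

test_that("relaxing any single criterion never removes a candidate", {
  ratios <- random_ratio_table(150, seed = 55)
  prot <- random_protein_table(unique(ratios$gene_id), seed = 55)
  base_cr <- filter_criteria()
  base <- apply_congruence_filter(ratios, prot, base_cr)$gene_id
  relaxed <- list(
    filter_criteria(min_fold_apc = 1.5),
    filter_criteria(alpha = 0.2),
    filter_criteria(apcmyc_wt_low = 0.5, apcmyc_wt_high = 1.5),
    filter_criteria(max_fold_apcmyc_apc = 0.8),
    filter_criteria(min_probes = 2),
    filter_criteria(min_protein_fold = 1.0))
  for (cr in relaxed) {
    wider <- apply_congruence_filter(ratios, prot, cr)$gene_id
    expect_true(all(base %in% wider))
  }
})

test_that("folds, p-values and candidates are invariant to global rescaling", {
  d <- generate_omics_dataset(omics_sim_config(n_genes = 15,
                                               n_planted_targets = 2),
                              seed = 31)
  r1 <- compute_genotype_ratios(d$expression, d$design)
  shifted <- d$expression
  samp <- d$design$sample
  shifted[, samp] <- shifted[, samp] + log2(7)  # times 7 on linear scale
  r2 <- compute_genotype_ratios(shifted, d$design)
  expect_equal(r1$fold_APC_WT, r2$fold_APC_WT, tolerance = 1e-12)
  expect_equal(r1$p_APC_WT, r2$p_APC_WT, tolerance = 1e-12)
  c1 <- apply_congruence_filter(r1, d$proteins)
  c2 <- apply_congruence_filter(r2, d$proteins)
  expect_identical(c1$gene_id, c2$gene_id)
})

test_that("fold_change_test matches exact enumeration and handles edge cases", {
  # identical multisets: fold 1, exact p 1
  r <- fold_change_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$mean_fold, 1.0)
  expect_equal(r$p_value, 1.0)

  # complete separation at n = 3 vs 3: exact p = 2 / C(6,3) = 0.1
  r2 <- fold_change_test(c(10, 11, 12), c(1, 2, 3))
  expect_equal(r2$p_value, 0.1)

  # doubling (distinct values): fold 2, p equals the enumeration oracle
  ctrl <- c(1.1, 2.3, 3.7, 4.9, 5.3)
  r3 <- fold_change_test(2 * ctrl, ctrl)
  expect_equal(r3$mean_fold, 2.0)
  expect_equal(r3$p_value, oracle_exact_mw_p(2 * ctrl, ctrl))

  # ties are handled by the exact path too
  case <- c(1, 2, 2, 5); ctl <- c(1, 2, 3)
  expect_equal(fold_change_test(case, ctl)$p_value,
               oracle_exact_mw_p(case, ctl))

  expect_error(fold_change_test(numeric(0), 1:3), "non-empty")
  expect_error(fold_change_test(1:3, c(-1, 0, 1)), "fold change undefined")
})

test_that("gene-mean filter mode accepts a gene whose probes pass only on average", {
  ratios <- data.frame(
    probe_id = paste0("p", 1:3), gene_id = "g1",
    fold_APC_WT = c(1.9, 2.6, 2.7), p_APC_WT = 0.01,
    ratio_APCMYC_WT = c(1.05, 0.95, 1.0),
    fold_APCMYC_APC = c(0.45, 0.4, 0.42), p_APCMYC_APC = 0.02,
    degenerate = FALSE)
  prot <- data.frame(protein_id = "P_g1", gene_id = "g1",
                     fold_APC_WT = 1.4)
  expect_equal(nrow(apply_congruence_filter(ratios, prot)), 0)
  gm <- apply_congruence_filter(ratios, prot, mode = "gene_mean")
  expect_equal(gm$gene_id, "g1")
})
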