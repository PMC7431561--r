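#' Per-probe genotype ratio statistics
#'
#' For every probe, computes linear fold changes between genotype means on
#' the log2 scale (`fold = 2^(mean log2 difference)`) for the three
#' contrasts used in the Myc-dependency screen — Apc-null vs wild-type
#' (APC:WT), double-null vs wild-type (APCMYC:WT), and double-null vs
#' Apc-null (APCMYC:APC) — with two-sided Welch t-test p-values on the log2
#' values for the APC:WT and APCMYC:APC contrasts. No multiplicity
#' adjustment is applied; the downstream filter consumes raw p-values.
#'
#' @param expr data.frame with columns `probe_id`, `gene_id` and one log2
#'   expression column per sample (an `omics_dataset$expression`).
#' @param design data.frame with columns `sample`, `genotype`; genotypes
#'   must include WT, APC and APCMYC with at least two replicates each.
#'
#' @return A data.frame of class `ratio_table` with columns `probe_id`,
#'   `gene_id`, `fold_APC_WT`, `p_APC_WT`, `ratio_APCMYC_WT`,
#'   `fold_APCMYC_APC`, `p_APCMYC_APC`, `degenerate` (TRUE where a
#'   zero-variance probe forced p = 1).
#' @export
compute_genotype_ratios <- function(expr, design) {
  needed <- c("probe_id", "gene_id")
  if (!all(needed %in% names(expr)))
    stop_input("expression table must have probe_id and gene_id columns")
  if (!all(c("sample", "genotype") %in% names(design)))
    stop_input("design must have sample and genotype columns")
  for (g in c("WT", "APC", "APCMYC")) {
    n <- sum(design$genotype == g)
    if (n < 2L)
      stop_input("design error: genotype ", g, " has ", n,
                 " replicates; at least 2 required")
  }
  missing_samples <- setdiff(design$sample, names(expr))
  if (length(missing_samples))
    stop_input("samples in design but not in expression table: ",
               paste(missing_samples, collapse = ", "))

  cols <- function(g) as.matrix(
    expr[, design$sample[design$genotype == g], drop = FALSE])
  wt <- cols("WT"); apc <- cols("APC"); apcmyc <- cols("APCMYC")

  welch_p <- function(x, y) {
    if (sd(x) < 1e-12 && sd(y) < 1e-12) return(NA_real_)
    t.test(x, y, var.equal = FALSE)$p.value
  }
  n <- nrow(expr)
  p1 <- p2 <- numeric(n)
  for (i in seq_len(n)) {
    p1[i] <- welch_p(apc[i, ], wt[i, ])
    p2[i] <- welch_p(apcmyc[i, ], apc[i, ])
  }
  degenerate <- is.na(p1) | is.na(p2)
  if (any(degenerate))
    warning(sum(degenerate),
            " zero-variance probe(s): p reported as 1", call. = FALSE)
  p1[is.na(p1)] <- 1; p2[is.na(p2)] <- 1

  out <- data.frame(
    probe_id = expr$probe_id, gene_id = expr$gene_id,
    fold_APC_WT = 2^(rowMeans(apc) - rowMeans(wt)),
    p_APC_WT = p1,
    ratio_APCMYC_WT = 2^(rowMeans(apcmyc) - rowMeans(wt)),
    fold_APCMYC_APC = 2^(rowMeans(apcmyc) - rowMeans(apc)),
    p_APCMYC_APC = p2,
    degenerate = degenerate,
    stringsAsFactors = FALSE
  )
  class(out) <- c("ratio_table", "data.frame")
  out
}

#' Criteria for the Myc-dependent Wnt-target congruence filter
#'
#' Defaults encode the published screen: a significant (p < 0.05) greater
#' than 2-fold APC:WT increase; an APCMYC:WT ratio within the 0.75-1.25
#' band (no significance requirement); a significant APCMYC:APC ratio below
#' 0.5; all three confirmed by at least 3 probes; and a protein fold above
#' 1.2 in the proteomic table.
#'
#' @param min_fold_apc minimum APC:WT fold (exclusive).
#' @param alpha significance level for the two tested contrasts.
#' @param apcmyc_wt_low,apcmyc_wt_high inclusive APCMYC:WT ratio band.
#' @param max_fold_apcmyc_apc maximum APCMYC:APC fold (exclusive).
#' @param min_probes minimum number of probes that must individually pass.
#' @param min_protein_fold minimum protein APC:WT fold (exclusive).
#' @return A list of class `filter_criteria`.
#' @export
filter_criteria <- function(min_fold_apc = 2.0, alpha = 0.05,
                            apcmyc_wt_low = 0.75, apcmyc_wt_high = 1.25,
                            max_fold_apcmyc_apc = 0.5, min_probes = 3L,
                            min_protein_fold = 1.2) {
  if (!(apcmyc_wt_low < 1 && 1 < apcmyc_wt_high))
    stop_input("the APCMYC:WT band must contain 1")
  if (alpha <= 0 || alpha >= 1) stop_input("alpha must be in (0, 1)")
  structure(list(min_fold_apc = min_fold_apc, alpha = alpha,
                 apcmyc_wt_low = apcmyc_wt_low,
                 apcmyc_wt_high = apcmyc_wt_high,
                 max_fold_apcmyc_apc = max_fold_apcmyc_apc,
                 min_probes = check_count(min_probes, "min_probes"),
                 min_protein_fold = min_protein_fold),
            class = "filter_criteria")
}

probe_passes <- function(ratios, criteria) {
  ratios$fold_APC_WT > criteria$min_fold_apc &
    ratios$p_APC_WT < criteria$alpha &
    ratios$ratio_APCMYC_WT >= criteria$apcmyc_wt_low &
    ratios$ratio_APCMYC_WT <= criteria$apcmyc_wt_high &
    ratios$fold_APCMYC_APC < criteria$max_fold_apcmyc_apc &
    ratios$p_APCMYC_APC < criteria$alpha
}

#' Apply the cross-omics congruence filter
#'
#' A gene is a candidate Myc-dependent Wnt target iff (a) at least
#' `min_probes` of its probes individually satisfy all three ratio criteria
#' — APC:WT fold above `min_fold_apc` with p below `alpha`; APCMYC:WT ratio
#' inside the band; APCMYC:APC fold below `max_fold_apcmyc_apc` with p below
#' `alpha` — and (b) a protein mapped to the gene (by shared `gene_id`) has
#' an APC:WT fold above `min_protein_fold`.
#'
#' The alternative `mode = "gene_mean"` evaluates the ratio criteria on
#' geometric-mean folds across a gene's probes (with the per-contrast median
#' p), for arrays where probe-level calls are too noisy.
#'
#' @param ratios a `ratio_table` from [compute_genotype_ratios()].
#' @param proteins data.frame `protein_id`, `gene_id`, `fold_APC_WT`.
#' @param criteria a [filter_criteria()].
#' @param mode `"probe"` (default, probe-level confirmation) or
#'   `"gene_mean"`.
#' @return A data.frame of class `candidate_list`: `gene_id`,
#'   `n_passing_probes`, `supporting_probes` (semicolon-separated),
#'   `protein_id`, `protein_fold`. Empty inputs give an empty list.
#' @export
apply_congruence_filter <- function(ratios, proteins,
                                    criteria = filter_criteria(),
                                    mode = c("probe", "gene_mean")) {
  mode <- match.arg(mode)
  stopifnot(inherits(criteria, "filter_criteria"))
  empty <- data.frame(gene_id = character(0),
                      n_passing_probes = integer(0),
                      supporting_probes = character(0),
                      protein_id = character(0),
                      protein_fold = numeric(0), stringsAsFactors = FALSE)
  class(empty) <- c("candidate_list", "data.frame")
  if (nrow(ratios) == 0L || nrow(proteins) == 0L) return(empty)

  unmapped <- !(proteins$gene_id %in% ratios$gene_id)
  if (any(unmapped))
    message(sum(unmapped), " protein(s) had no gene in the ratio table ",
            "and were ignored")
  prot_ok <- proteins[proteins$fold_APC_WT > criteria$min_protein_fold &
                        !unmapped, , drop = FALSE]

  if (mode == "gene_mean") {
    agg <- do.call(rbind, lapply(split(ratios, ratios$gene_id), function(d)
      data.frame(gene_id = d$gene_id[1],
                 fold_APC_WT = 2^mean(log2(d$fold_APC_WT)),
                 p_APC_WT = median(d$p_APC_WT),
                 ratio_APCMYC_WT = 2^mean(log2(d$ratio_APCMYC_WT)),
                 fold_APCMYC_APC = 2^mean(log2(d$fold_APCMYC_APC)),
                 p_APCMYC_APC = median(d$p_APCMYC_APC),
                 n_probes = nrow(d),
                 probes = paste(d$probe_id, collapse = ";"),
                 stringsAsFactors = FALSE)))
    ok <- probe_passes(agg, criteria) & agg$n_probes >= criteria$min_probes
    pass_by_gene <- agg[ok, , drop = FALSE]
    genes <- pass_by_gene$gene_id
    n_pass <- pass_by_gene$n_probes
    support <- pass_by_gene$probes
  } else {
    pass <- probe_passes(ratios, criteria)
    d <- ratios[pass, , drop = FALSE]
    tab <- table(d$gene_id)
    genes <- as.character(names(tab)[tab >= criteria$min_probes])
    n_pass <- as.integer(tab[genes])
    support <- vapply(genes, function(g)
      paste(d$probe_id[d$gene_id == g], collapse = ";"), character(1))
  }

  keep <- genes %in% prot_ok$gene_id
  genes <- genes[keep]; n_pass <- n_pass[keep]; support <- support[keep]
  pi <- match(genes, prot_ok$gene_id)
  out <- data.frame(gene_id = genes, n_passing_probes = n_pass,
                    supporting_probes = support,
                    protein_id = prot_ok$protein_id[pi],
                    protein_fold = prot_ok$fold_APC_WT[pi],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_list", "data.frame")
  out
}

# Exact two-sided rank-sum p by full enumeration of group assignments:
# twice the smaller tail probability, capped at 1. Handles ties (midranks);
# used for small samples where the normal approximation is poor.
exact_ranksum_p <- function(case, control) {
  n1 <- length(case); n <- n1 + length(control)
  r <- rank(c(case, control))
  w_obs <- sum(r[seq_len(n1)])
  sets <- combn(n, n1)
  w_all <- apply(sets, 2, function(ix) sum(r[ix]))
  min(1, 2 * min(mean(w_all <= w_obs + 1e-12),
                 mean(w_all >= w_obs - 1e-12)))
}

#' Tumor-vs-normal fold change with a Mann-Whitney test
#'
#' Computes the mean fold change (mean of case values over mean of control
#' values, on the linear scale) and a two-sided Mann-Whitney U p-value:
#' exact by full enumeration when the combined sample size is at most 12
#' (valid under ties), otherwise the tie-corrected normal approximation.
#'
#' @param case_values,control_values positive linear-scale expression
#'   values; typically normalized so that the control mean defines 1.
#' @return A list of class `fold_change_result`: `mean_fold`, `p_value`,
#'   `method`, `n_case`, `n_control`.
#' @export
#' @examples
#' fold_change_test(c(2, 3, 4), c(1, 1.2, 0.8))
fold_change_test <- function(case_values, control_values) {
  if (length(case_values) == 0L || length(control_values) == 0L)
    stop_input("both groups must be non-empty")
  if (mean(control_values) == 0)
    stop_input("control mean is 0: fold change undefined")
  n <- length(case_values) + length(control_values)
  if (n <= 12L) {
    p <- exact_ranksum_p(case_values, control_values)
    method <- "exact enumeration"
  } else {
    p <- wilcox.test(case_values, control_values, exact = FALSE,
                     correct = FALSE)$p.value
    method <- "normal approximation (tie-corrected)"
  }
  structure(list(mean_fold = mean(case_values) / mean(control_values),
                 p_value = p, method = method,
                 n_case = length(case_values),
                 n_control = length(control_values)),
            class = "fold_change_result")
}
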