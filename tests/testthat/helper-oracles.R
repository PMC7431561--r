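# Independent brute-force oracles used to cross-check the implementation.
# These re-derive each quantity from first principles and deliberately share
# no code with the package.

# Welch two-sample t-test p-value from the textbook formulas.
oracle_welch_p <- function(x, y) {
  v1 <- var(x) / length(x); v2 <- var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  2 * pt(-abs(tstat), df)
}

# Exact two-sided rank-sum p as twice the smaller tail of the enumerated
# permutation distribution (capped at 1).
oracle_exact_mw_p <- function(case, control) {
  n1 <- length(case); n <- n1 + length(control)
  r <- rank(c(case, control))
  w <- sum(r[seq_len(n1)])
  w_all <- apply(combn(n, n1), 2, function(ix) sum(r[ix]))
  min(1, 2 * min(mean(w_all <= w + 1e-12), mean(w_all >= w - 1e-12)))
}

# AUC as brute-force pair-counting concordance: ties get half credit.
oracle_concordance <- function(scores, outcome) {
  pos <- scores[as.logical(outcome)]
  neg <- scores[!as.logical(outcome)]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Hand-tabulated two-group log-rank statistic (hypergeometric variance at
# each distinct event time).
oracle_logrank_chisq <- function(times, events, group) {
  group <- as.integer(factor(group))
  ev_times <- sort(unique(times[events == 1]))
  o_minus_e <- 0; v <- 0
  for (t in ev_times) {
    at_risk <- times >= t
    n_j <- sum(at_risk)
    n1_j <- sum(at_risk & group == 1L)
    d_j <- sum(times == t & events == 1)
    d1_j <- sum(times == t & events == 1 & group == 1L)
    o_minus_e <- o_minus_e + d1_j - d_j * n1_j / n_j
    if (n_j > 1)
      v <- v + d_j * (n1_j / n_j) * (1 - n1_j / n_j) *
        (n_j - d_j) / (n_j - 1)
  }
  o_minus_e^2 / v
}

# Hand product-limit estimator at each event time.
oracle_km <- function(times, events) {
  ts <- sort(unique(times[events == 1]))
  s <- 1
  vapply(ts, function(t) {
    n <- sum(times >= t); d <- sum(times == t & events == 1)
    s <<- s * (1 - d / n)
    s
  }, numeric(1))
}

# Two-sided Fisher exact p for a 2x2 table by full hypergeometric
# enumeration: sum the probabilities of all tables (with the observed
# margins) no more probable than the observed one.
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(ks, c1, n - c1, r1)
  p_obs <- dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Brute-force four-zone pixel tally on the 0-255 DAB intensity axis.
oracle_zone_fractions <- function(dab_od, z) {
  i <- pmin(pmax(255 * 10^(-as.vector(dab_od)), 0), 255)
  c(neg = mean(i > z[3]),
    low = mean(i > z[2] & i <= z[3]),
    pos = mean(i > z[1] & i <= z[2]),
    high = mean(i <= z[1]))
}

# Brute-force re-evaluation of the congruence predicate, gene by gene.
oracle_congruence <- function(ratios, proteins, cr) {
  genes <- unique(ratios$gene_id)
  keep <- vapply(genes, function(g) {
    d <- ratios[ratios$gene_id == g, ]
    npass <- 0
    for (i in seq_len(nrow(d))) {
      ok <- d$fold_APC_WT[i] > cr$min_fold_apc &&
        d$p_APC_WT[i] < cr$alpha &&
        d$ratio_APCMYC_WT[i] >= cr$apcmyc_wt_low &&
        d$ratio_APCMYC_WT[i] <= cr$apcmyc_wt_high &&
        d$fold_APCMYC_APC[i] < cr$max_fold_apcmyc_apc &&
        d$p_APCMYC_APC[i] < cr$alpha
      if (ok) npass <- npass + 1
    }
    if (npass < cr$min_probes) return(FALSE)
    any(proteins$gene_id == g &
          proteins$fold_APC_WT > cr$min_protein_fold)
  }, logical(1))
  sort(genes[keep])
}

# Small random ratio table for filter fuzzing.
random_ratio_table <- function(n_genes, probes = 3, seed) {
  set.seed(seed)
  gene <- rep(sprintf("g%03d", seq_len(n_genes)), each = probes)
  n <- length(gene)
  out <- data.frame(
    probe_id = paste0(gene, "_p", seq_len(probes)),
    gene_id = gene,
    fold_APC_WT = 2^runif(n, -2, 3),
    p_APC_WT = runif(n),
    ratio_APCMYC_WT = 2^runif(n, -1, 1),
    fold_APCMYC_APC = 2^runif(n, -2, 1),
    p_APCMYC_APC = runif(n),
    degenerate = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("ratio_table", "data.frame")
  out
}

random_protein_table <- function(genes, seed) {
  set.seed(seed + 1)
  data.frame(protein_id = paste0("P_", genes), gene_id = genes,
             fold_APC_WT = 2^runif(length(genes), -1, 1.5),
             stringsAsFactors = FALSE)
}
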