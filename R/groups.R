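#' Group comparison tests used across the study
#'
#' Dispatches the comparisons used for continuous and categorical
#' clinicopathological variables:
#' \describe{
#'   \item{`mann_whitney`}{two-group tie-corrected Mann-Whitney U
#'     ([stats::wilcox.test()], normal approximation).}
#'   \item{`kruskal_wallis_dunn`}{tie-corrected Kruskal-Wallis
#'     ([stats::kruskal.test()]) plus Dunn pairwise z-tests with
#'     Bonferroni-adjusted p-values (capped at 1).}
#'   \item{`chi_square`}{Pearson chi-square without continuity correction,
#'     switching automatically to Fisher's exact test when any expected
#'     cell count is below 5.}
#'   \item{`fisher_exact`}{Fisher's exact test directly.}
#' }
#' All p-values are two-sided.
#'
#' @param values for rank tests, a numeric vector; for categorical tests, a
#'   vector of category labels (or a pre-tabulated contingency matrix, with
#'   `group_labels` omitted).
#' @param group_labels group membership vector, same length as `values`.
#' @param kind one of `"mann_whitney"`, `"kruskal_wallis_dunn"`,
#'   `"chi_square"`, `"fisher_exact"`.
#' @return A list of class `group_test`: `statistic` (NA for Fisher),
#'   `p_value`, `method`, and for the Dunn post hoc a `pairwise` data.frame
#'   (`group1`, `group2`, `z`, `p_adjusted`).
#' @export
#' @examples
#' compare_groups(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3),
#'                "mann_whitney")
compare_groups <- function(values, group_labels = NULL,
                           kind = c("mann_whitney", "kruskal_wallis_dunn",
                                    "chi_square", "fisher_exact")) {
  kind <- match.arg(kind)
  if (kind %in% c("mann_whitney", "kruskal_wallis_dunn")) {
    g <- factor(group_labels)
    if (nlevels(g) < 2L) stop_input("at least two groups required")
    if (kind == "mann_whitney") {
      if (nlevels(g) != 2L)
        stop_input("mann_whitney requires exactly two groups")
      wt <- wilcox.test(values ~ g, exact = FALSE, correct = FALSE)
      return(structure(list(statistic = unname(wt$statistic),
                            p_value = wt$p.value,
                            method = "Mann-Whitney U (tie-corrected)"),
                       class = "group_test"))
    }
    kw <- kruskal.test(values, g)
    pw <- dunn_posthoc(values, g)
    return(structure(list(statistic = unname(kw$statistic),
                          p_value = kw$p.value,
                          method = "Kruskal-Wallis + Dunn-Bonferroni",
                          pairwise = pw), class = "group_test"))
  }

  tab <- if (is.matrix(values) || is.table(values)) as.matrix(values)
         else table(values, group_labels)
  if (any(dim(tab) < 2L)) stop_input("contingency table needs >= 2x2 cells")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  use_fisher <- kind == "fisher_exact" || any(expected < 5)
  if (use_fisher) {
    ft <- fisher.test(tab)
    method <- if (kind == "chi_square")
      "Fisher's exact (expected count < 5)" else "Fisher's exact"
    structure(list(statistic = NA_real_, p_value = ft$p.value,
                   method = method), class = "group_test")
  } else {
    ct <- chisq.test(tab, correct = FALSE)
    structure(list(statistic = unname(ct$statistic), p_value = ct$p.value,
                   method = "Pearson chi-square"), class = "group_test")
  }
}

# Dunn pairwise z-tests on midranks with the tie correction shared across
# comparisons; Bonferroni adjustment over all pairs, capped at 1.
dunn_posthoc <- function(values, g) {
  r <- rank(values)
  n <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  lv <- levels(g)
  pairs <- combn(lv, 2)
  ncomp <- ncol(pairs)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    z = NA_real_, p_adjusted = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(ncomp)) {
    i <- g == pairs[1, k]; j <- g == pairs[2, k]
    ni <- sum(i); nj <- sum(j)
    z <- (mean(r[i]) - mean(r[j])) /
      sqrt((n * (n + 1) / 12 - tie_term) * (1 / ni + 1 / nj))
    out$z[k] <- z
    out$p_adjusted[k] <- min(1, 2 * pnorm(-abs(z)) * ncomp)
  }
  out
}
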