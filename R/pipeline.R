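# End-to-end flows: discovery (omics -> candidate list) and prognosis
# (cohort -> scored survival report), each with a run manifest.

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop_input(what, " file not found: ", path)
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop_input(what, " (", path, ") is missing required column(s): ",
               paste(miss, collapse = ", "))
  d
}

digest_by_name <- function(paths) {
  paths <- paths[file.exists(paths)]
  d <- tools::md5sum(paths)
  names(d) <- basename(paths)
  as.list(d)
}

build_manifest <- function(config, seed, inputs, outputs, timings,
                           warnings) {
  list(
    package = "crcmark",
    version = as.character(packageVersion("crcmark")),
    seed = seed,
    config = config,
    input_digests = digest_by_name(inputs),
    output_digests = digest_by_name(outputs),
    timings_sec = timings,
    warnings = unique(warnings)
  )
}

#' Run the discovery flow: expression + protein tables to candidate list
#'
#' Reads a probe-level expression table, a sample-genotype design and a
#' protein fold table, computes the genotype ratio statistics, applies the
#' congruence filter and writes `ratio_table.tsv`, `candidates.tsv`,
#' `candidates.json` and `manifest.json` under `out_dir`.
#'
#' @param config a list (or path to a YAML/JSON file) with elements
#'   `expression`, `design`, `proteins` (input paths), `out_dir`, and
#'   optionally `criteria` (arguments for [filter_criteria()]), `mode`
#'   (probe/gene_mean) and `seed`.
#' @return Invisibly, a list with `candidates`, `ratios` and `manifest`.
#' @export
run_discovery <- function(config) {
  config <- load_config(config)
  for (f in c("expression", "design", "proteins", "out_dir"))
    if (is.null(config[[f]])) stop_input("config is missing '", f, "'")
  t0 <- proc.time()[["elapsed"]]
  warns <- character(0)
  withCallingHandlers({
    expr <- read_tsv_checked(config[["expression"]], c("probe_id", "gene_id"),
                             "expression table")
    design <- read_tsv_checked(config[["design"]], c("sample", "genotype"),
                               "design table")
    proteins <- read_tsv_checked(config[["proteins"]],
                                 c("protein_id", "gene_id", "fold_APC_WT"),
                                 "protein table")
    criteria <- do.call(filter_criteria, as.list(config[["criteria"]]))
    ratios <- compute_genotype_ratios(expr, design)
    candidates <- apply_congruence_filter(
      ratios, proteins, criteria, mode = config[["mode"]] %||% "probe")
  }, warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  dir.create(config[["out_dir"]], showWarnings = FALSE, recursive = TRUE)
  p_ratio <- file.path(config[["out_dir"]], "ratio_table.tsv")
  p_cand <- file.path(config[["out_dir"]], "candidates.tsv")
  p_cand_json <- file.path(config[["out_dir"]], "candidates.json")
  p_manifest <- file.path(config[["out_dir"]], "manifest.json")
  write.table(ratios, p_ratio, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(as.data.frame(candidates), p_cand, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(
    n_candidates = nrow(candidates),
    candidates = as.data.frame(candidates),
    criteria = unclass(criteria),
    test = "Welch two-sample t on log2 values, two-sided, unadjusted"
  ), p_cand_json, digits = NA, auto_unbox = TRUE)
  manifest <- build_manifest(
    config, config[["seed"]] %||% NA,
    inputs = c(config[["expression"]], config[["design"]], config[["proteins"]]),
    outputs = c(p_ratio, p_cand, p_cand_json),
    timings = list(total = proc.time()[["elapsed"]] - t0),
    warnings = warns)
  jsonlite::write_json(manifest, p_manifest, digits = NA,
                       auto_unbox = TRUE, force = TRUE)
  message(nrow(candidates), " candidate(s) written to ", config[["out_dir"]])
  invisible(list(candidates = candidates, ratios = ratios,
                 manifest = manifest))
}

#' Run the prognosis flow: scored cohort to survival report
#'
#' Takes a patient cohort (CSV path or `patient_cohort` data.frame) with
#' per-patient scores, selects a cutoff against mortality status,
#' dichotomizes, and produces ROC/AUC, Kaplan-Meier curves (whole cohort
#' and early/late stage subgroups), log-rank tests and a multivariate Cox
#' table (score group, age, sex, stage, grade). Results are written as JSON
#' and Markdown with a manifest; KM and ROC figures as SVG.
#'
#' @param config a list (or YAML/JSON path) with `cohort` (path or
#'   data.frame), `out_dir`, and optionally `score` (column name, default
#'   `"nuclear_pct"`), `cutoff_method` (default `"balanced"`), `cutoff`
#'   (fixed value overriding the scan), `plots` (default TRUE), `seed`.
#' @return Invisibly, a list with `cutoff`, `groups`, `km`, `logrank`,
#'   `cox`, `report`, `manifest`.
#' @export
run_prognosis <- function(config) {
  config <- load_config(config)
  if (is.null(config[["out_dir"]])) stop_input("config is missing 'out_dir'")
  t0 <- proc.time()[["elapsed"]]
  warns <- character(0)
  cohort_path <- NULL
  cohort <- config[["cohort"]]
  if (is.character(cohort)) {
    cohort_path <- cohort
    cohort <- read_cohort(cohort)
  }
  if (is.null(cohort)) stop_input("config is missing 'cohort'")
  score_col <- config[["score"]] %||% "nuclear_pct"
  if (!score_col %in% names(cohort))
    stop_input("score column '", score_col, "' not in cohort")
  scores <- cohort[[score_col]]
  outcome <- as.logical(cohort$event)

  withCallingHandlers({
    roc <- roc_curve(scores, outcome)
    cut <- if (!is.null(config[["cutoff"]])) {
      grp0 <- scores >= config[["cutoff"]]
      pred <- if (roc$auc < 0.5) !grp0 else grp0
      list(cutoff = config[["cutoff"]],
           sensitivity = sum(pred & outcome) / sum(outcome),
           specificity = sum(!pred & !outcome) / sum(!outcome),
           method = "fixed", direction = if (roc$auc < 0.5) "<" else ">=")
    } else {
      select_cutoff(scores, outcome,
                    method = config[["cutoff_method"]] %||% "balanced",
                    times = cohort$time_months, events = cohort$event)
    }
    group <- factor(ifelse(scores >= cut$cutoff, "high", "low"),
                    levels = c("low", "high"))
    cohort$score_group <- group

    analyse <- function(d) {
      if (min(table(factor(d$score_group,
                           levels = c("low", "high")))) < 2L)
        return(list(estimable = FALSE))
      km <- lapply(split(d, d$score_group), function(s)
        km_estimate(s$time_months, s$event))
      lr <- logrank(d$time_months, d$event, d$score_group)
      list(estimable = TRUE, km = km, logrank = lr,
           five_year = lapply(km, function(k) k$surv_at(60)),
           median = lapply(km, function(k) k$median))
    }
    whole <- analyse(cohort)
    early <- analyse(cohort[cohort$stage_group == "early", , drop = FALSE])
    late <- analyse(cohort[cohort$stage_group == "late", , drop = FALSE])
    cov_use <- intersect(c("score_group", "age", "sex", "stage_group",
                           "grade"), names(cohort))
    cov_use <- cov_use[vapply(cov_use, function(cn)
      length(unique(cohort[[cn]][!is.na(cohort[[cn]])])) > 1L,
      logical(1))]
    cox <- if (sum(cohort$event) > 0 && whole$estimable)
      cox_ph(cohort, cov_use) else NULL
  }, warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  dir.create(config[["out_dir"]], showWarnings = FALSE, recursive = TRUE)
  report <- list(
    n_patients = nrow(cohort), n_events = sum(cohort$event),
    score = score_col, auc = roc$auc,
    cutoff = cut[c("cutoff", "sensitivity", "specificity", "method")],
    group_sizes = as.list(table(cohort$score_group)),
    survival = list(
      whole = strip_km(whole), early_stage = strip_km(early),
      late_stage = strip_km(late)),
    cox = if (!is.null(cox))
      c(list(ties = cox$ties, converged = cox$converged),
        list(table = cox$table)) else "not estimable"
  )
  p_json <- file.path(config[["out_dir"]], "prognosis_report.json")
  p_md <- file.path(config[["out_dir"]], "prognosis_report.md")
  p_manifest <- file.path(config[["out_dir"]], "manifest.json")
  jsonlite::write_json(report, p_json, digits = NA, auto_unbox = TRUE,
                       force = TRUE)
  writeLines(format_prognosis_md(report), p_md)
  outputs <- c(p_json, p_md)
  if (isTRUE(config[["plots"]] %||% TRUE)) {
    p_km <- file.path(config[["out_dir"]], "km_curves.svg")
    p_roc <- file.path(config[["out_dir"]], "roc_curve.svg")
    plot_km_svg(cohort, p_km)
    plot_roc_svg(roc, p_roc)
    outputs <- c(outputs, p_km, p_roc)
  }
  manifest <- build_manifest(
    config[setdiff(names(config), "cohort")], config[["seed"]] %||% NA,
    inputs = cohort_path %||% character(0), outputs = outputs,
    timings = list(total = proc.time()[["elapsed"]] - t0),
    warnings = warns)
  jsonlite::write_json(manifest, p_manifest, digits = NA,
                       auto_unbox = TRUE, force = TRUE)
  invisible(list(cutoff = cut, cohort = cohort,
                 whole = whole, early = early, late = late,
                 cox = cox, roc = roc, report = report,
                 manifest = manifest))
}

strip_km <- function(a) {
  if (!isTRUE(a$estimable))
    return(list(estimable = FALSE, note = "not estimable: a score group has fewer than 2 patients"))
  list(estimable = TRUE,
       logrank_p = a$logrank$p_value,
       logrank_chisq = a$logrank$statistic,
       five_year_survival = a$five_year,
       median_months = lapply(a$median, function(m)
         if (is.na(m)) "not reached" else m))
}

format_prognosis_md <- function(r) {
  fmt_surv <- function(s, name) {
    if (!isTRUE(s$estimable))
      return(c(paste0("## ", name), s$note, ""))
    c(paste0("## ", name),
      sprintf("- log-rank chi-square %.3f, p = %.4g",
              s$logrank_chisq, s$logrank_p),
      sprintf("- 5-year survival: low %.1f%%, high %.1f%%",
              100 * s$five_year_survival$low,
              100 * s$five_year_survival$high),
      sprintf("- median survival (months): low %s, high %s",
              format(s$median_months$low), format(s$median_months$high)),
      "")
  }
  out <- c("# Prognosis report", "",
           sprintf("- patients: %d (%d events)", r$n_patients, r$n_events),
           sprintf("- score: %s; AUC = %.3f", r$score, r$auc),
           sprintf("- cutoff: %.3f (%s); sensitivity %.2f, specificity %.2f",
                   r$cutoff$cutoff, r$cutoff$method, r$cutoff$sensitivity,
                   r$cutoff$specificity),
           sprintf("- groups: low n = %d, high n = %d",
                   r$group_sizes$low, r$group_sizes$high), "",
           fmt_surv(r$survival$whole, "Whole cohort"),
           fmt_surv(r$survival$early_stage, "Early stage (I-II)"),
           fmt_surv(r$survival$late_stage, "Late stage (III-IV)"))
  if (is.list(r$cox)) {
    tab <- r$cox$table
    out <- c(out, "## Multivariate Cox", "",
             "| term | HR | 95% CI | p |", "|---|---|---|---|",
             sprintf("| %s | %.3f | %.3f-%.3f | %.4g |", tab$term,
                     tab$hazard_ratio, tab$ci95_low, tab$ci95_high,
                     tab$p_value))
  } else {
    out <- c(out, "## Multivariate Cox", "", r$cox)
  }
  out
}

plot_km_svg <- function(cohort, path) {
  grDevices::svg(path, width = 7, height = 5)
  on.exit(grDevices::dev.off())
  fit <- survival::survfit(
    survival::Surv(time_months, event) ~ score_group, data = cohort)
  plot(fit, col = c("firebrick", "steelblue"), lwd = 2, mark.time = TRUE,
       xlab = "Months", ylab = "Cumulative survival")
  graphics::legend("bottomleft", legend = c("low", "high"),
                   col = c("firebrick", "steelblue"), lwd = 2, bty = "n")
  invisible(path)
}

plot_roc_svg <- function(roc, path) {
  grDevices::svg(path, width = 5, height = 5)
  on.exit(grDevices::dev.off())
  plot(roc$points$fpr, roc$points$tpr, type = "s", lwd = 2,
       xlab = "1 - specificity", ylab = "Sensitivity",
       main = sprintf("AUC = %.3f", roc$auc))
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(path)
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_input("config file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop_input("config must be a list or a file path")
  config
}
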