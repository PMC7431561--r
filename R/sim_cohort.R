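#' Configuration for the synthetic prognostic cohort generator
#'
#' Emulates a 75-patient colorectal-cancer prognostic cohort: demographic
#' margins (57.3% male, 62.7% late stage, mean age 59.7 years within 33-84,
#' grade mix 30.7/66.7/2.6%), a bimodal nuclear score whose two modes define
#' latent low/high expression groups, and exponential survival with a
#' protective hazard ratio for the high-expression group plus
#' administrative censoring.
#'
#' @param n_patients cohort size.
#' @param male_fraction,stage_late_fraction Bernoulli margins for sex and
#'   late (III-IV) stage.
#' @param age_mean,age_min,age_max,age_sd truncated-normal age distribution
#'   in years.
#' @param grade_fractions three fractions (well, moderate, poor) summing
#'   to 1.
#' @param high_score_fraction fraction of patients in the latent
#'   high-nuclear-score group.
#' @param baseline_hazard events per month in the low-score group; the
#'   default `log(2)/32` puts the low group's median survival at 32 months.
#' @param hr_high_vs_low_nuclear hazard ratio of the high group vs the low
#'   group; values below 1 mean high expression is protective.
#' @param censor_time_months administrative censoring horizon.
#' @param score_group_separation distance in percentage points between the
#'   two nuclear-score group means.
#' @param nuclear_low_mean,nuclear_sd nuclear-score mode location/spread.
#' @param hscore_low_mean,hscore_separation,hscore_sd cytoplasmic modified
#'   H-score mode location, group separation and spread.
#'
#' @return A list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_patients = 75, male_fraction = 0.573,
                              stage_late_fraction = 0.627,
                              age_mean = 59.7, age_min = 33, age_max = 84,
                              age_sd = 11,
                              grade_fractions = c(well = 0.307,
                                                  moderate = 0.667,
                                                  poor = 0.026),
                              high_score_fraction = 41 / 75,
                              baseline_hazard = log(2) / 32,
                              hr_high_vs_low_nuclear = 0.39,
                              censor_time_months = 120,
                              score_group_separation = 30,
                              nuclear_low_mean = 20, nuclear_sd = 8,
                              hscore_low_mean = 110,
                              hscore_separation = 40, hscore_sd = 35) {
  n_patients <- check_count(n_patients, "n_patients")
  check_fraction(male_fraction, "male_fraction")
  check_fraction(stage_late_fraction, "stage_late_fraction")
  check_fraction(high_score_fraction, "high_score_fraction")
  if (!(age_min <= age_mean && age_mean <= age_max))
    stop_input("need age_min <= age_mean <= age_max")
  if (length(grade_fractions) != 3L ||
      abs(sum(grade_fractions) - 1) > 1e-6)
    stop_input("grade_fractions must be 3 values summing to 1")
  check_positive(baseline_hazard, "baseline_hazard")
  check_positive(hr_high_vs_low_nuclear, "hr_high_vs_low_nuclear")
  if (censor_time_months < 0)
    stop_input("censor_time_months must be nonnegative")
  structure(list(
    n_patients = n_patients, male_fraction = male_fraction,
    stage_late_fraction = stage_late_fraction,
    age_mean = age_mean, age_min = age_min, age_max = age_max,
    age_sd = age_sd, grade_fractions = grade_fractions,
    high_score_fraction = high_score_fraction,
    baseline_hazard = baseline_hazard,
    hr_high_vs_low_nuclear = hr_high_vs_low_nuclear,
    censor_time_months = censor_time_months,
    score_group_separation = score_group_separation,
    nuclear_low_mean = nuclear_low_mean, nuclear_sd = nuclear_sd,
    hscore_low_mean = hscore_low_mean,
    hscore_separation = hscore_separation, hscore_sd = hscore_sd
  ), class = "cohort_sim_config")
}

#' Generate a synthetic prognostic patient cohort
#'
#' Covariates are drawn to match the configured margins; nuclear scores are
#' bimodal with the configured group separation; survival times are
#' exponential with hazard `baseline_hazard * hr^(group == high)` so that a
#' hazard ratio below 1 favours the high-expression group; administrative
#' censoring at `censor_time_months` sets the event flag.
#'
#' @param cfg a [cohort_sim_config()].
#' @param seed integer seed; identical `(cfg, seed)` give identical output.
#' @return A data.frame of class `patient_cohort` with columns `id`, `age`,
#'   `sex`, `stage_group`, `grade`, `nuclear_pct`, `cytoplasmic_hscore`,
#'   `time_months`, `event`, and the latent truth column `true_group`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_sim_config(), seed = 42)
#' nrow(coh)
generate_cohort <- function(cfg = cohort_sim_config(), seed) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  with_seed(seed, {
    n <- cfg$n_patients
    age <- pmin(pmax(rnorm(n, cfg$age_mean, cfg$age_sd), cfg$age_min),
                cfg$age_max)
    sex <- factor(ifelse(runif(n) < cfg$male_fraction, "male", "female"),
                  levels = c("female", "male"))
    stage <- factor(ifelse(runif(n) < cfg$stage_late_fraction,
                           "late", "early"), levels = c("early", "late"))
    grade <- factor(sample(c("well", "moderate", "poor"), n, replace = TRUE,
                           prob = cfg$grade_fractions),
                    levels = c("well", "moderate", "poor"))
    group <- factor(ifelse(runif(n) < cfg$high_score_fraction,
                           "high", "low"), levels = c("low", "high"))
    high_mean <- cfg$nuclear_low_mean + cfg$score_group_separation
    nuclear <- rnorm(n, ifelse(group == "high", high_mean,
                               cfg$nuclear_low_mean), cfg$nuclear_sd)
    nuclear <- pmin(pmax(nuclear, 0), 100)
    hsc <- rnorm(n, cfg$hscore_low_mean +
                   ifelse(group == "high", cfg$hscore_separation, 0),
                 cfg$hscore_sd)
    hsc <- pmin(pmax(hsc, 0), 300)
    hazard <- cfg$baseline_hazard *
      cfg$hr_high_vs_low_nuclear^(group == "high")
    t_raw <- rexp(n, rate = hazard)
    time <- pmin(t_raw, cfg$censor_time_months)
    event <- as.integer(t_raw <= cfg$censor_time_months &
                          cfg$censor_time_months > 0)
    out <- data.frame(id = sprintf("pt%03d", seq_len(n)), age = age,
                      sex = sex, stage_group = stage, grade = grade,
                      nuclear_pct = nuclear, cytoplasmic_hscore = hsc,
                      time_months = time, event = event,
                      true_group = group, stringsAsFactors = FALSE)
    class(out) <- c("patient_cohort", "data.frame")
    out
  })
}

#' Read / write a patient cohort CSV
#'
#' Column dictionary: `id`, `age` (years), `sex` (female/male),
#' `stage_group` (early = I-II, late = III-IV), `grade`
#' (well/moderate/poor), `nuclear_pct` (0-100), `cytoplasmic_hscore`
#' (0-300), `time_months` (>= 0), `event` (1 = death, 0 = censored).
#'
#' @param path CSV file.
#' @return `read_cohort`: a `patient_cohort` data.frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_input("cohort file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("id", "age", "sex", "stage_group", "grade", "nuclear_pct",
              "cytoplasmic_hscore", "time_months", "event")
  miss <- setdiff(needed, names(d))
  if (length(miss))
    stop_input("cohort CSV is missing columns: ",
               paste(miss, collapse = ", "))
  if (any(d$time_months < 0)) stop_input("negative time_months in cohort")
  d$sex <- factor(d$sex, levels = c("female", "male"))
  d$stage_group <- factor(d$stage_group, levels = c("early", "late"))
  d$grade <- factor(d$grade, levels = c("well", "moderate", "poor"))
  class(d) <- c("patient_cohort", "data.frame")
  d
}

#' @rdname read_cohort
#' @param cohort a `patient_cohort` data.frame.
#' @export
write_cohort <- function(cohort, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}
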