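# crcmark

Cross-omics biomarker discovery and digital immunohistochemistry (IHC)
prognosis for colorectal cancer.

Colorectal tumors are initiated by *APC* loss, which activates Wnt
signalling with *MYC* as an essential effector. One route to new prognostic
biomarkers is to screen knockout-mouse models for proteins whose induction
under Apc loss is Myc-dependent, then quantify the candidate on stained
patient sections and ask whether its expression predicts survival. crcmark
implements that full arc as a tested, reusable R pipeline, with seeded
synthetic generators standing in for the mouse arrays, the stained
sections, and the patient cohort so that every stage is verifiable without
external data.

## What it computes

**Discovery — the congruence filter.** From a probe-level expression table
over four genotypes (WT, Apc-null, Apc/Myc-null, Myc-null; fold changes as
`2^(difference of log2 means)`, Welch t-tests on log2 values), a gene is a
candidate Myc-dependent Wnt target iff at least 3 probes each satisfy

- APC:WT fold > 2 with p < 0.05,
- APCMYC:WT ratio in [0.75, 1.25],
- APCMYC:APC fold < 0.5 with p < 0.05,

and a protein mapped to the gene shows > 1.2-fold APC:WT increase in the
proteomic table.

**Scoring — two numbers per stained section.** After Beer–Lambert colour
deconvolution with the Ruifrok–Johnston H-DAB basis:

- cytoplasmic *modified H-score* = 0·%negative + 100·%low-positive +
  200·%positive + 300·%high-positive over four DAB intensity zones
  (cutpoints 60/120/180 on the 0–255 axis), range 0–300;
- nuclear *positive percentage* = 100 × (#nuclei with mean DAB OD above a
  threshold) / (#nuclei), range 0–100, with Otsu + connected-components
  segmentation.

**Prognosis.** ROC/AUC against mortality, cutoff selection by
sensitivity–specificity balance (Youden and log-rank scan as
alternatives), Kaplan–Meier curves with median and 5-year survival,
log-rank tests, and multivariate Cox (Efron ties) over score group, age,
sex, stage and grade — for the whole cohort and early/late stage
subgroups.

## Worked example

```r
library(crcmark)

# --- discovery on a seeded synthetic screen with two planted targets
d <- generate_omics_dataset(omics_sim_config(n_genes = 50,
                                             n_planted_targets = 2),
                            seed = 42)
ratios <- compute_genotype_ratios(d$expression, d$design)
apply_congruence_filter(ratios, d$proteins)
#>    gene_id n_passing_probes                      supporting_probes protein_id
#> 1 gene0001                3 gene0001_at1;gene0001_at2;gene0001_at3 P_gene0001
#> 2 gene0002                3 gene0002_at1;gene0002_at2;gene0002_at3 P_gene0002
#>   protein_fold
#> 1     1.487481
#> 2     1.530040
```

Both planted genes — and nothing else — pass all three ratio criteria on
all three probes and carry protein support above 1.2-fold.

```r
# --- score a synthetic H-DAB section
im <- generate_ihc_image(image_sim_config(positive_nucleus_fraction = 0.4),
                         seed = 7)
od  <- deconvolve_hdab(im$image)
lab <- segment_nuclei(od)
nuclear_positive_fraction(lab, od$dab_od)
#> [1] 40
```

The recovered nuclear percentage matches the planted truth (40% of nuclei
were given strong DAB).

```r
# --- prognosis on a synthetic 75-patient cohort
coh <- generate_cohort(cohort_sim_config(), seed = 42)
cut <- select_cutoff(coh$nuclear_pct, coh$event)   # balanced method
cut$cutoff; cut$sensitivity; cut$specificity
#> [1] 46.54934
#> [1] 0.6851852
#> [1] 0.6666667

coh$score_group <- factor(ifelse(coh$nuclear_pct >= cut$cutoff,
                                 "high", "low"), levels = c("low", "high"))
logrank(coh$time_months, coh$event, coh$score_group)$p_value
#> [1] 0.004143454

cox_ph(coh, c("score_group", "age", "sex", "stage_group", "grade"))$table
#>              term hazard_ratio ci95_low ci95_high p_value
#> 1 score_grouphigh        0.365    0.200     0.667 0.00105
#> 2             age        0.985    0.959     1.011 0.24898
#> 3         sexmale        0.451    0.244     0.835 0.01131
#> 4 stage_grouplate        1.065    0.541     2.094 0.85579
#> 5   grademoderate        1.430    0.760     2.690 0.26791
#> 6       gradepoor        8.478    1.989    36.128 0.00385
```

The cohort was generated with a protective hazard ratio of 0.39 for the
high-nuclear-expression group; the fitted score-group HR of 0.365 (95% CI
0.20–0.67) recovers it, and the log-rank test separates the groups at
p ≈ 0.004. `run_prognosis()` wraps this whole flow (plus stage subgroups,
KM/ROC figures and a manifest) around a cohort CSV, and `run_discovery()`
does the same for the filter; `inst/scripts/crcmark.R` exposes both as
shell subcommands.

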