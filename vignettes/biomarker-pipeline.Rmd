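---
title: "From knockout screens to survival curves: the crcmark methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From knockout screens to survival curves: the crcmark methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcmark)
```

crcmark implements the analysis arc of a tissue-biomarker study in
colorectal cancer: nominate candidate Myc-dependent Wnt-target proteins by
intersecting knockout-mouse transcriptomics with proteomics, quantify the
candidate's expression on stained patient sections with digital scoring,
and relate the resulting scores to overall survival. This vignette explains
each model, its assumptions, the tunable parameters, and the design choices
made where the design was genuinely open.

## The discovery model: a cross-omics congruence filter

The discovery substrate is a four-genotype small-intestine expression
experiment: wild type (WT), Apc-null (APC), Apc/Myc double-null (APCMYC)
and Myc-null (MYC), with four biological replicates per genotype. Apc loss
activates Wnt signalling; a gene is a *Myc-dependent* Wnt target if its
induction under Apc loss disappears when Myc is co-deleted. The filter
encodes exactly that signature, per probe:

1. APC:WT fold $> 2$ with $p < 0.05$ (induction under Apc loss);
2. APCMYC:WT ratio inside $[0.75, 1.25]$ (expression back at baseline when
   Myc is also gone; a band, with no significance requirement);
3. APCMYC:APC fold $< 0.5$ with $p < 0.05$ (the drop itself is
   significant);

with a gene retained only when **at least three probes** individually pass
all three criteria *and* a protein mapped to the gene shows an APC:WT fold
above 1.2 in the proteomic table.

Expression is handled on the log2 scale throughout; a fold change is
$2^{\bar x_A - \bar x_B}$ for genotype means $\bar x$. The two tested
contrasts use a two-sided Welch (unequal-variance) t-test on the log2
values — the natural default for 4-vs-4 microarray replicates — and the
test identity is echoed in the candidate report. P-values are deliberately
**unadjusted**: the filter is a conjunction of hard criteria across two
omics layers, which is itself a stringent multiplicity control, and the
thresholds above are part of the method's definition. A zero-variance probe
(possible in synthetic data) reports $p = 1$ with a `degenerate` flag
rather than failing.

Reading "confirmed by at least three probes" as *each probe individually
passes* is the strict interpretation; an alternative `gene_mean` mode
evaluates the criteria on geometric-mean folds across the gene's probes
(with the per-contrast median p) for platforms whose individual probes are
too noisy. The probe-level mode is the default because it is the harder
test and matches the redundancy requirement's intent.

Tumor-vs-normal qPCR comparisons use `fold_change_test()`: the mean fold on
the linear scale (control mean defining 1) with a two-sided Mann–Whitney U
p-value — exact by full enumeration of group assignments when the combined
sample size is at most 12 (the enumeration uses midranks, so ties are
handled), otherwise the tie-corrected normal approximation.

## The scoring model: H-DAB sections to two numbers per sample

A section stained with hematoxylin (blue, nuclei) and DAB (brown, antibody
signal) mixes stains linearly in optical-density space (Beer–Lambert). With
channel OD $-\log_{10}((I_c + 1)/256)$ and the Ruifrok–Johnston H-DAB basis
(hematoxylin $\approx (0.650, 0.704, 0.286)$, DAB $\approx (0.269, 0.568,
0.778)$, third vector their normalized cross product), inverting the stain
matrix yields per-pixel hematoxylin and DAB concentrations; negative
concentrations are clamped to zero. The $+1$ in the OD transform avoids
$\log 0$ at black pixels and costs at most about 0.01 OD of bias over the
range the scorer uses.

**Cytoplasmic score.** DAB OD is mapped back to a 0–255 intensity
($I = 255 \cdot 10^{-\mathrm{OD}}$) and binned into four zones at cutpoints
60/120/180 (the IHC Profiler convention; configurable): high-positive
$[0, 60]$, positive $(60, 120]$, low-positive $(120, 180]$, negative
$(180, 255]$. The modified H-score is the weighted composition

$$H = 0\cdot f_{neg} + 100\cdot f_{low} + 200\cdot f_{pos} + 300\cdot f_{high} \in [0, 300].$$

**Nuclear score.** Nuclei are segmented by an Otsu threshold on total stain
OD (hematoxylin + DAB) restricted to tissue, followed by connected-component
labelling with a minimum area of 12 pixels. A nucleus is *positive* when its
mean DAB OD exceeds 0.15 (default; declared in output metadata rather than
asserted as any tool's internal setting), and the nuclear score is
$100 \times \#\text{positive}/\#\text{nuclei}$. This counts nuclei, which
is what "percentage of positive nuclei" means; an area-based variant
(DAB-positive nuclear area over total nuclear area, the ImmunoRatio native
reading) is available via `mode = "area"`. Tissue is any pixel with total
OD above 0.08 — glass and mounting medium sit well below this — and an
explicit mask can be supplied instead, mirroring the practice of manually
excluding stroma.

**Field protocol.** A sample is scored from at least two ×400 fields of at
least 100 detected cells each; per-field scores are averaged (pooling
across fields is available via `pool_fields = TRUE`; averaging is the
default since replicate fields are equally informative). A low cell count
raises a warning, upgraded to an error in strict mode; fewer than two
fields is always an error. No watershed splitting is applied by default —
the synthetic nuclei are non-touching — but a watershed flag exists for
real material.

## The prognostic model: cutoff, Kaplan–Meier, Cox

Scores are dichotomized against mortality status. Candidate cutoffs are
midpoints between adjacent distinct scores; the default `balanced` method
minimizes $|\text{sensitivity} - \text{specificity}|$, with Youden's index
and a log-rank scan as alternatives, ties breaking toward the lower
cutoff. The high group is `score >= cutoff`. Because a protective marker
(higher score, longer survival) has AUC below 0.5 against mortality, the
`auto` direction predicts death from *low* scores in that case; cohort
cutoffs are always inputs to downstream analyses, never hard-coded.

Survival uses the standard machinery of the `survival` package behind a
stable interface: the product-limit estimator (median = smallest $t$ with
$S(t) \le 0.5$; $S(60)$ read as the 5-year survival when time is in
months), the log-rank test with hypergeometric variance, and Cox
proportional-hazards regression with Efron tie handling (Breslow by flag;
recorded in metadata), Wald 95% intervals exponentiated from the log-hazard
scale, and convergence to $10^{-8}$ or a flag. Categorical covariates are
expanded against fixed references: female, early stage (I–II), well
differentiated, low score group. Stage enters as the early/late binary —
the grouping the prognostic analyses report — not as four levels. Subgroup
analyses re-run the same machinery on the stage strata; no interaction
terms are modelled. Across endpoints no multiplicity adjustment is applied
(only the Dunn post hoc adjusts, within its own family), and reports say
so.

Group comparisons elsewhere follow the field's defaults: Mann–Whitney or
Kruskal–Wallis with Dunn–Bonferroni post hoc for continuous variables;
chi-square for categorical tables, switching to Fisher's exact test
whenever any expected cell count falls below 5.

## What the synthetic generators emulate — and what they do not

All three generators take a configuration object plus one integer seed;
every stochastic draw flows from that seed, and equal (config, seed) give
bit-identical output. The generator defaults *are* the study conditions the
package is tested under.

**Omics** (`generate_omics_dataset()`): gene baselines
$\mathcal N(7, 1)$ on log2, probe-specific affinity offsets
$\mathcal N(0, 0.2)$, measurement noise $\mathcal N(0, 0.1)$, 3 probes per
gene, 4 replicates per genotype. Planted targets carry a $\log_2 4$ shift
in the APC genotype only, so their expected APCMYC:WT ratio is 1 — the
Myc-dependency signature by construction. The protein table holds planted
proteins at 1.5-fold (safely above the 1.2 criterion, as iTRAQ ratios
compress true fold changes) and decoys near 1, both with 0.05 log2-scale
spread. Not emulated: probe cross-hybridisation, array normalization
artefacts, batch effects, or correlated noise — so the planted-truth
recovery rate speaks to the filter's logic, not to its behaviour on raw
array data.

**Images** (`generate_ihc_image()`): a tissue disc on near-white glass;
non-overlapping elliptical nuclei (semi-axes 3–6 px, random orientation,
placed by rejection sampling with a bounded retry budget that fails loudly
naming `n_nuclei`); cytoplasm pixels partitioned *exactly* (to within one
pixel) into the four intensity classes at planted DAB ODs 0.02/0.18/
0.42/0.75 — chosen to land inside the four default zones after the OD →
intensity mapping; nuclear hematoxylin OD 1.2, so nuclei are the darkest
objects on the section, as hematoxylin-counterstained nuclei are in
practice and as intensity-based segmentation requires; positive nuclei add
DAB at OD 0.8. The image is composed per pixel and channel as
$255 \cdot 10^{-(c_h S_h + c_d S_d)}$ with the same stain basis the scorer
inverts — so the deconvolution round-trip error reflects only 8-bit
quantization (mean absolute DAB-OD error is about 0.004, comfortably
within the 0.02 contract). Not emulated: tissue texture, stain variability
across labs, touching nuclei, scanner noise, FFPE artefacts. Scoring-chain
recovery on these images validates the pipeline's arithmetic and
segmentation logic, not robustness to real-world staining.

**Cohort** (`generate_cohort()`): margins follow the prognostic cohort's
descriptive table — n = 75, 57.3% male, 62.7% late stage, age truncated
normal with mean 59.7 on [33, 84] (SD 11, a stand-in; the source reports
only mean and range), grade mix 30.7/66.7/2.6%. The nuclear score is a
two-component normal: low mode 20, separation 30 (placing the modes around
the published 32% cutoff scale), SD 8, clamped to [0, 100]; the latent
group indicator (high with probability 41/75) is carried in the output as
`true_group` for recovery studies. Survival is exponential with baseline
hazard $\log 2 / 32$ per month — the low group's median of 32 months —
multiplied by a hazard ratio of 0.39 for the high group (both defaults from
the published prognostic estimates), with administrative censoring at 120
months (the follow-up window spanned 48–153 months, median 84.7).
Exponential survival and independent censoring are idealisations; the
generator supports Cox/log-rank calibration checks, not clinical
realism.

## Numerical choices and degenerate inputs

* Folds are geometric (means of log2 values), so global rescaling of
  linear expression changes nothing — a tested invariant.
* The Otsu threshold is computed only over tissue pixels (256 levels over
  the observed range); an all-flat field returns an empty labelling rather
  than a spurious one.
* `censor_time_months = 0` produces an all-censored cohort; the KM wrapper
  flags it (`degenerate = TRUE`, median undefined) instead of erroring, and
  the prognosis report marks inestimable survival sections explicitly.
* Cutoff ties break toward the lower cutoff; exact Mann–Whitney p-values
  are twice the smaller enumerated tail, capped at 1.
* Cox non-convergence and separation are surfaced as flags on the result,
  never silently.
* The label raster of a synthetic image is written as 16-bit grayscale
  TIFF (the available PNG writers are 8-bit-only); the stained image itself
  is 8-bit RGB PNG.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated data at
deliberately modest sizes: 160×160-pixel sections with 20–40 nuclei,
50-gene × 3-probe arrays over 16 samples, 75-patient cohorts for
calibration loops (1000 replicates under the null), and 2000-patient
cohorts for hazard-ratio recovery (100 seeds). These sizes give the
property checks stable pass/fail behaviour while keeping a full run in the
low minutes on a single core.

## Known limitations

* The congruence filter consumes pre-summarised probe expression and
  protein folds; array normalization and mass-spec quantification are out
  of scope.
* Segmentation is threshold-plus-components; densely touching nuclei need
  the watershed flag and even then real chromatin texture will challenge
  it.
* The prognostic layer implements the analyses a single-cohort study
  reports: no competing risks, no time-varying covariates, no
  cross-validated cutoff correction. Cutoffs chosen on a cohort and
  evaluated on the same cohort are optimistic by construction; treat them
  as descriptive.
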