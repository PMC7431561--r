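#' Configuration for the synthetic multi-omics generator
#'
#' Describes a four-genotype knockout expression experiment (wild-type,
#' Apc-null, Apc/Myc double-null, Myc-null) with a known set of planted
#' Myc-dependent Wnt-target genes, plus an overlapping protein fold-change
#' table standing in for an iTRAQ screen.
#'
#' @param n_genes number of genes on the array.
#' @param n_planted_targets number of planted Myc-dependent targets
#'   (`<= n_genes`).
#' @param probes_per_gene probes per gene; a single count (default 3, the
#'   minimum probe redundancy the discovery filter requires) or a vector of
#'   length `n_genes`.
#' @param replicates_per_genotype biological replicates per genotype
#'   (default 4, four mice in each group).
#' @param effect_fold_apc linear fold change of planted targets in Apc-null
#'   vs wild-type.
#' @param noise_sd per-measurement Gaussian noise on the log2 scale.
#' @param protein_overlap_fraction fraction of planted genes whose protein
#'   appears in the protein fold table.
#' @param protein_fold_planted linear Apc-null:WT protein fold for planted
#'   proteins.
#' @param n_decoy_proteins number of decoy proteins (non-planted genes) with
#'   folds near 1.
#' @param decoy_fold_sd log2-scale spread of decoy / planted protein folds
#'   around their targets.
#' @param baseline_log2_mean,baseline_log2_sd distribution of gene baseline
#'   log2 expression.
#'
#' @return A list of class `omics_sim_config`.
#' @export
omics_sim_config <- function(n_genes = 50, n_planted_targets = 5,
                             probes_per_gene = 3,
                             replicates_per_genotype = 4,
                             effect_fold_apc = 4, noise_sd = 0.1,
                             protein_overlap_fraction = 1,
                             protein_fold_planted = 1.5,
                             n_decoy_proteins = 20,
                             decoy_fold_sd = 0.05,
                             baseline_log2_mean = 7, baseline_log2_sd = 1) {
  n_genes <- check_count(n_genes, "n_genes")
  n_planted_targets <- check_count(n_planted_targets, "n_planted_targets",
                                   min = 0L)
  if (n_planted_targets > n_genes)
    stop_input("n_planted_targets must not exceed n_genes")
  replicates_per_genotype <- check_count(replicates_per_genotype,
                                         "replicates_per_genotype", min = 2L)
  if (length(probes_per_gene) == 1L)
    probes_per_gene <- rep(check_count(probes_per_gene, "probes_per_gene"),
                           n_genes)
  if (length(probes_per_gene) != n_genes || any(probes_per_gene < 1))
    stop_input("probes_per_gene must be a positive count or one per gene")
  check_positive(effect_fold_apc, "effect_fold_apc")
  check_positive(noise_sd, "noise_sd")
  check_fraction(protein_overlap_fraction, "protein_overlap_fraction")
  check_positive(protein_fold_planted, "protein_fold_planted")
  n_decoy_proteins <- check_count(n_decoy_proteins, "n_decoy_proteins",
                                  min = 0L)
  structure(list(
    n_genes = n_genes, n_planted_targets = n_planted_targets,
    probes_per_gene = as.integer(probes_per_gene),
    replicates_per_genotype = replicates_per_genotype,
    effect_fold_apc = effect_fold_apc, noise_sd = noise_sd,
    protein_overlap_fraction = protein_overlap_fraction,
    protein_fold_planted = protein_fold_planted,
    n_decoy_proteins = n_decoy_proteins, decoy_fold_sd = decoy_fold_sd,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd
  ), class = "omics_sim_config")
}

GENOTYPES <- c("WT", "APC", "APCMYC", "MYC")

#' Generate a synthetic probe-expression table and protein fold table
#'
#' Expression is generated and stored on the log2 scale. Planted target genes
#' carry a `log2(effect_fold_apc)` shift in the Apc-null genotype only: their
#' expected Apc-null:WT fold is `effect_fold_apc` on every probe, while the
#' double-null:WT fold stays at 1 (the Myc-dependency signature). Non-planted
#' genes have expected fold 1 in every contrast. The protein table contains
#' the planted proteins at `protein_fold_planted` plus decoys near 1, linked
#' to genes by a shared `gene_id`.
#'
#' @param cfg an [omics_sim_config()].
#' @param seed integer seed; identical `(cfg, seed)` give identical output.
#'
#' @return A list of class `omics_dataset`:
#' \describe{
#'   \item{expression}{data.frame `probe_id`, `gene_id`, one log2 column per
#'     sample.}
#'   \item{design}{data.frame `sample`, `genotype` (WT/APC/APCMYC/MYC).}
#'   \item{proteins}{data.frame `protein_id`, `gene_id`, `fold_APC_WT`
#'     (linear scale).}
#'   \item{truth}{list `planted_gene_ids`, `planted_protein_ids`.}
#' }
#' @export
#' @examples
#' d <- generate_omics_dataset(omics_sim_config(n_genes = 10), seed = 1)
#' head(d$expression[, 1:4])
generate_omics_dataset <- function(cfg = omics_sim_config(), seed) {
  stopifnot(inherits(cfg, "omics_sim_config"))
  with_seed(seed, {
    genes <- sprintf("gene%04d", seq_len(cfg$n_genes))
    planted <- genes[seq_len(cfg$n_planted_targets)]
    probe_gene <- rep(genes, times = cfg$probes_per_gene)
    probes <- paste0(probe_gene, "_at",
                     unlist(lapply(cfg$probes_per_gene, seq_len)))

    reps <- cfg$replicates_per_genotype
    design <- data.frame(
      sample = paste0(rep(GENOTYPES, each = reps), "_", seq_len(reps)),
      genotype = rep(GENOTYPES, each = reps),
      stringsAsFactors = FALSE
    )

    baseline_gene <- rnorm(cfg$n_genes, cfg$baseline_log2_mean,
                           cfg$baseline_log2_sd)
    names(baseline_gene) <- genes
    # probe-specific affinity offsets, constant across samples
    probe_offset <- rnorm(length(probes), 0, 0.2)

    shift <- ifelse(design$genotype == "APC", log2(cfg$effect_fold_apc), 0)
    is_planted <- probe_gene %in% planted

    mu <- outer(baseline_gene[probe_gene] + probe_offset,
                rep(0, nrow(design)), `+`)
    mu <- mu + outer(as.numeric(is_planted), shift)
    expr <- mu + matrix(rnorm(length(mu), 0, cfg$noise_sd), nrow = nrow(mu))
    colnames(expr) <- design$sample

    expression <- data.frame(probe_id = probes, gene_id = probe_gene,
                             expr, stringsAsFactors = FALSE,
                             check.names = FALSE)
    rownames(expression) <- NULL

    n_overlap <- ceiling(cfg$protein_overlap_fraction *
                           cfg$n_planted_targets)
    planted_prot_genes <- planted[seq_len(n_overlap)]
    decoy_pool <- setdiff(genes, planted)
    decoy_genes <- decoy_pool[seq_len(min(cfg$n_decoy_proteins,
                                          length(decoy_pool)))]
    prot_genes <- c(planted_prot_genes, decoy_genes)
    fold <- c(
      cfg$protein_fold_planted *
        2^rnorm(length(planted_prot_genes), 0, cfg$decoy_fold_sd),
      2^rnorm(length(decoy_genes), 0, cfg$decoy_fold_sd)
    )
    proteins <- data.frame(
      protein_id = paste0("P_", prot_genes),
      gene_id = prot_genes,
      fold_APC_WT = fold,
      stringsAsFactors = FALSE
    )

    structure(list(
      expression = expression, design = design, proteins = proteins,
      truth = list(planted_gene_ids = planted,
                   planted_protein_ids = paste0("P_", planted_prot_genes))
    ), class = "omics_dataset")
  })
}

#' Write an omics dataset to headered TSV files
#'
#' Writes `expression.tsv`, `design.tsv`, `proteins.tsv` and `truth.json`
#' under `dir`.
#'
#' @param dataset an `omics_dataset` from [generate_omics_dataset()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_omics_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "omics_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    design = file.path(dir, "design.tsv"),
    proteins = file.path(dir, "proteins.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write.table(dataset$expression, paths[["expression"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(dataset$design, paths[["design"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(dataset$proteins, paths[["proteins"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(dataset$truth, paths[["truth"]])
  invisible(paths)
}
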