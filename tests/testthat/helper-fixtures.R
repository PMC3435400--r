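# Small deterministic fixtures, built in code.

# Manifest of n probes; the first n_x on chromosome X, the next n_snp
# flagged as SNP-containing.
toy_manifest <- function(n, n_x = 0, n_snp = 0) {
  stopifnot(n_x + n_snp <= n)
  chrom <- rep("1", n)
  if (n_x > 0) chrom[seq_len(n_x)] <- "X"
  snp <- rep(FALSE, n)
  if (n_snp > 0) snp[n_x + seq_len(n_snp)] <- TRUE
  probe_manifest(data.frame(
    probe_id = sprintf("p%04d", seq_len(n)),
    target_id = sprintf("G%04d_%s%d_%s", seq_len(n),
                        rep(c("E", "P"), length.out = n), seq_len(n),
                        rep(c("F", "R"), length.out = n)),
    chromosome = chrom, snp_in_probe = snp, stringsAsFactors = FALSE))
}

toy_sheet <- function(n_subjects, phenos = "healthy", batches = "b1") {
  subj <- sprintf("s%03d", seq_len(n_subjects))
  sample_sheet(data.frame(
    sample_id = paste0(rep(subj, each = 2), "_", c("AEC", "PBMC")),
    subject_id = rep(subj, each = 2),
    cell_type = rep(c("AEC", "PBMC"), n_subjects),
    phenotype = rep(rep(phenos, length.out = n_subjects), each = 2),
    batch = rep(rep(batches, length.out = n_subjects), each = 2),
    sex = "unknown", age = 8, stringsAsFactors = FALSE))
}

# Deterministic intensity dataset: n probes x (2 * n_subjects) samples.
toy_dataset <- function(n_probes, n_subjects, n_x = 0, n_snp = 0,
                        phenos = "healthy", batches = "b1", seed = 7) {
  man <- toy_manifest(n_probes, n_x, n_snp)
  sheet <- toy_sheet(n_subjects, phenos, batches)
  ns <- nrow(sheet)
  set.seed(seed)
  dn <- list(man$probe_id, sheet$sample_id)
  cy5 <- matrix(stats::runif(n_probes * ns, 100, 5000), n_probes, ns,
                dimnames = dn)
  cy3 <- matrix(stats::runif(n_probes * ns, 100, 5000), n_probes, ns,
                dimnames = dn)
  dp <- matrix(stats::runif(n_probes * ns, 0, 0.04), n_probes, ns,
               dimnames = dn)
  intensity_dataset(man, sheet, cy5, cy3, dp)
}

# Simulation config for a compact two-group experiment (shared by the
# calibration and recovery tests).
experiment_config <- function(seed, n_probes = 1000, n_truth = 0,
                              effect = 6, n_per_group = 10) {
  sim_config(n_probes = n_probes, n_x_probes = 0, n_snp_probes = 0,
             n_subjects_per_phenotype = c(healthy = n_per_group,
                                          atopic = n_per_group),
             n_celltype_diff_probes = 0,
             n_phenotype_diff_probes = n_truth,
             phenotype_effect = effect,
             phenotype_affected = "atopic", phenotype_cell_type = "AEC",
             seed = seed)
}

aec_comparison <- list(list(name = "aec_healthy_vs_atopic",
                            stratum = list(cell_type = "AEC"),
                            variable = "phenotype",
                            levels = c("healthy", "atopic")))
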