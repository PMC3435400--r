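#' Simulation configuration for a matched two-tissue methylation study
#'
#' Defaults emulate a paediatric airway study design: a 1505-probe CpG
#' cancer panel (84 X-chromosome probes, 272 SNP-containing probes), 25
#' subjects split 7 healthy / 9 atopic / 4 atopic-asthmatic / 5
#' non-atopic-asthmatic, each contributing one AEC and one PBMC sample,
#' about 0.5% detection-failed data points, and two processing batches.
#'
#' Effect sizes are mean shifts on the M-value scale, applied as
#' methylation-state switches (an unmethylated probe gains methylation in
#' the affected group, a methylated one loses it).  Per-probe baselines
#' come from a two-component mixture (mostly-unmethylated around
#' `m_unmeth`, mostly-methylated around `m_meth`), giving a per-sample
#' M-value spread of roughly 2 units; the default switch magnitude of 6
#' M-units (beta moving from about 0.2 to about 0.95) injects z-score
#' differences of roughly 2.2-3 after preprocessing, i.e. on the scale at
#' which panel studies report differential methylation (raw z-differences
#' of 2-2.5, or 1-1.3 on the log2 axis).
#'
#' @param n_probes total probes on the panel.
#' @param n_subjects_per_phenotype named integer vector over
#'   [phenotype_levels()]; phenotypes may be 0.
#' @param n_x_probes,n_snp_probes probes placed on chromosome X /
#'   flagged as SNP-containing (disjoint; their sum must not exceed
#'   `n_probes`).
#' @param frac_detection_failed target fraction of (probe, sample) entries
#'   with detection p-value > 0.05.
#' @param n_celltype_diff_probes,celltype_effect number of probes carrying
#'   a cell-type difference and the M-value shift applied to AEC samples
#'   (shift direction switches the probe toward its opposite methylation
#'   state).
#' @param n_phenotype_diff_probes,phenotype_effect number of probes
#'   carrying a phenotype difference and its M-value shift, applied in
#'   `phenotype_cell_type` samples of subjects whose phenotype is in
#'   `phenotype_affected`.
#' @param phenotype_affected phenotypes receiving the phenotype effect.
#' @param phenotype_cell_type cell type in which the phenotype effect acts.
#' @param n_batches number of processing batches (subjects assigned
#'   round-robin; both samples of a subject share a batch).
#' @param batch_shift M-scale magnitude of the batch displacement, applied
#'   along a fixed random unit direction over probes.
#' @param noise_sd per-entry Gaussian noise SD on the M scale.
#' @param meth_fraction,m_unmeth,m_meth,m_component_sd baseline mixture:
#'   fraction of mostly-methylated probes, the two component means and the
#'   within-component SD (M scale).
#' @param intensity_scale overall intensity scale `s` used when
#'   back-transforming to channel intensities.
#' @param intensity_noise_sd_log2 SD of the shared per-entry log2
#'   brightness factor applied to both channels.
#' @param seed master seed; one derived stream per logical component
#'   (manifest, cohort, baseline, effects, batch, noise, intensity,
#'   detection) so that changing one field perturbs only its component.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_probes = 1505,
                       n_subjects_per_phenotype = c(healthy = 7, atopic = 9,
                                                    atopic_asthmatic = 4,
                                                    nonatopic_asthmatic = 5),
                       n_x_probes = 84, n_snp_probes = 272,
                       frac_detection_failed = 0.005,
                       n_celltype_diff_probes = 80, celltype_effect = 6,
                       n_phenotype_diff_probes = 8, phenotype_effect = 6,
                       phenotype_affected = c("atopic_asthmatic",
                                              "nonatopic_asthmatic"),
                       phenotype_cell_type = "AEC",
                       n_batches = 2, batch_shift = 2.5,
                       noise_sd = 0.5,
                       meth_fraction = 0.3, m_unmeth = -2, m_meth = 2,
                       m_component_sd = 0.5,
                       intensity_scale = 2000,
                       intensity_noise_sd_log2 = 0.25,
                       seed = 1) {
  cfg <- list(n_probes = as.integer(n_probes),
              n_subjects_per_phenotype = n_subjects_per_phenotype,
              n_x_probes = as.integer(n_x_probes),
              n_snp_probes = as.integer(n_snp_probes),
              frac_detection_failed = frac_detection_failed,
              n_celltype_diff_probes = as.integer(n_celltype_diff_probes),
              celltype_effect = celltype_effect,
              n_phenotype_diff_probes = as.integer(n_phenotype_diff_probes),
              phenotype_effect = phenotype_effect,
              phenotype_affected = phenotype_affected,
              phenotype_cell_type = phenotype_cell_type,
              n_batches = as.integer(n_batches),
              batch_shift = batch_shift,
              noise_sd = noise_sd,
              meth_fraction = meth_fraction, m_unmeth = m_unmeth,
              m_meth = m_meth, m_component_sd = m_component_sd,
              intensity_scale = intensity_scale,
              intensity_noise_sd_log2 = intensity_noise_sd_log2,
              seed = as.integer(seed))
  with(cfg, {
    if (n_probes < 1L) stop("n_probes must be >= 1", call. = FALSE)
    if (n_x_probes < 0L || n_snp_probes < 0L ||
        n_x_probes + n_snp_probes > n_probes)
      stop("need n_x_probes + n_snp_probes <= n_probes, both >= 0",
           call. = FALSE)
    if (!all(names(n_subjects_per_phenotype) %in% phenotype_levels()))
      stop("unknown phenotype in n_subjects_per_phenotype", call. = FALSE)
    if (sum(n_subjects_per_phenotype) < 1L)
      stop("at least one subject required", call. = FALSE)
    if (frac_detection_failed < 0 || frac_detection_failed > 1)
      stop("frac_detection_failed must lie in [0,1]", call. = FALSE)
    n_auto <- n_probes - n_x_probes - n_snp_probes
    if (n_celltype_diff_probes + n_phenotype_diff_probes > n_auto)
      stop("more effect probes than autosomal non-SNP probes", call. = FALSE)
    if (!phenotype_cell_type %in% c("AEC", "PBMC"))
      stop("phenotype_cell_type must be 'AEC' or 'PBMC'", call. = FALSE)
    if (n_batches < 1L) stop("n_batches must be >= 1", call. = FALSE)
    if (noise_sd <= 0 || intensity_scale <= 0)
      stop("noise_sd and intensity_scale must be positive", call. = FALSE)
    if (meth_fraction < 0 || meth_fraction > 1)
      stop("meth_fraction must lie in [0,1]", call. = FALSE)
  })
  class(cfg) <- "sim_config"
  cfg
}

# Derived per-component seeds (kept below 2^31).
component_seeds <- function(seed) {
  comps <- c("manifest", "cohort", "baseline", "effects", "batch", "noise",
             "intensity", "detection")
  s <- (as.double(seed) * 2654435761 + seq_along(comps) * 40503) %% 2147483647
  stats::setNames(as.integer(s), comps)
}

#' Simulate a matched two-tissue methylation intensity dataset
#'
#' Generates an [intensity_dataset()] with the structure the analysis
#' pipeline assumes, together with a truth table recording which probes
#' carry injected effects.  Each subject contributes one AEC and one PBMC
#' sample.  Per-probe baseline M-values are drawn from a two-component
#' mixture; designated cell-type-differential probes get `+/-
#' celltype_effect` added in AEC samples, designated phenotype-differential
#' probes get `+/- phenotype_effect` in the configured cell type and
#' phenotypes, batch displacements are added along a fixed random unit
#' direction on the M scale, and per-entry Gaussian noise is added.
#' M-values are then back-transformed to channel intensities via
#' `beta = 2^M / (2^M + 1)`, `Cy5 = s * beta * 2^a`,
#' `Cy3 = s * (1 - beta) * 2^a` with a shared per-entry log2 brightness
#' `a`; this inversion shares no code with the pipeline's forward M-value
#' computation, so the generator is an independent oracle for it.
#' Detection p-values are sampled so that on average
#' `frac_detection_failed` of entries exceed 0.05, independently of
#' methylation state.
#'
#' @param config a [sim_config()].
#' @return A list with elements `dataset` (an `intensity_dataset`),
#'   `truth` (data.frame `probe_id`, `effect` = `"celltype"`/`"phenotype"`,
#'   `direction` = `"more_methylated"`/`"less_methylated"` in the affected
#'   group, `magnitude`), and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  seeds <- component_seeds(cfg$seed)
  np <- cfg$n_probes

  ## --- manifest ----------------------------------------------------------
  set.seed(seeds[["manifest"]])
  probe_id <- sprintf("probe%05d", seq_len(np))
  gene <- sprintf("GENE%04d", ceiling(seq_len(np) / 2))  # ~2 CpGs per gene
  region <- sample(c("E", "P"), np, replace = TRUE)
  tssd <- sample.int(1500L, np, replace = TRUE)
  strand <- sample(c("F", "R"), np, replace = TRUE)
  chrom <- sample(as.character(1:22), np, replace = TRUE)
  x_idx <- seq_len(cfg$n_x_probes)
  if (cfg$n_x_probes > 0L) chrom[x_idx] <- "X"
  snp <- rep(FALSE, np)
  if (cfg$n_snp_probes > 0L)
    snp[cfg$n_x_probes + seq_len(cfg$n_snp_probes)] <- TRUE
  man <- probe_manifest(data.frame(
    probe_id = probe_id,
    target_id = format_target_id(gene, region, tssd, strand),
    chromosome = chrom, snp_in_probe = snp, stringsAsFactors = FALSE))

  ## --- cohort ------------------------------------------------------------
  set.seed(seeds[["cohort"]])
  nsub <- cfg$n_subjects_per_phenotype
  nsub <- nsub[nsub > 0]
  phen <- rep(names(nsub), times = nsub)
  n_subjects <- length(phen)
  subj <- sprintf("subj%03d", seq_len(n_subjects))
  sex <- sample(c("M", "F"), n_subjects, replace = TRUE, prob = c(0.6, 0.4))
  age <- round(stats::runif(n_subjects, 2, 15), 1)
  batch <- paste0("batch", ((seq_len(n_subjects) - 1L) %% cfg$n_batches) + 1L)
  sheet <- data.frame(
    sample_id = paste0(rep(subj, each = 2L), "_", c("AEC", "PBMC")),
    subject_id = rep(subj, each = 2L),
    cell_type = rep(c("AEC", "PBMC"), times = n_subjects),
    phenotype = rep(phen, each = 2L),
    batch = rep(batch, each = 2L),
    sex = rep(sex, each = 2L),
    age = rep(age, each = 2L), stringsAsFactors = FALSE)
  sheet <- sample_sheet(sheet)
  ns <- nrow(sheet)

  ## --- baseline M-values -------------------------------------------------
  set.seed(seeds[["baseline"]])
  is_meth <- stats::runif(np) < cfg$meth_fraction
  base_m <- ifelse(is_meth, cfg$m_meth, cfg$m_unmeth) +
    stats::rnorm(np, 0, cfg$m_component_sd)
  M <- matrix(base_m, np, ns, dimnames = list(probe_id, sheet$sample_id))

  ## --- injected effects --------------------------------------------------
  set.seed(seeds[["effects"]])
  eligible <- which(chrom != "X" & !snp)
  picked <- sample(eligible,
                   cfg$n_celltype_diff_probes + cfg$n_phenotype_diff_probes)
  ct_idx <- picked[seq_len(cfg$n_celltype_diff_probes)]
  ph_idx <- picked[cfg$n_celltype_diff_probes +
                     seq_len(cfg$n_phenotype_diff_probes)]
  truth <- data.frame(probe_id = character(), effect = character(),
                      direction = character(), magnitude = numeric(),
                      stringsAsFactors = FALSE)
  # Effects are methylation-state switches: an unmethylated probe gains
  # methylation in the affected group and a methylated probe loses it.
  # This keeps the shifted beta-values inside the array's dynamic range
  # (a shift further into a saturated tail would be unobservable by
  # construction of the beta scale).
  if (length(ct_idx)) {
    sgn <- ifelse(is_meth[ct_idx], -1, 1)
    aec <- sheet$cell_type == "AEC"
    M[ct_idx, aec] <- M[ct_idx, aec] + sgn * cfg$celltype_effect
    truth <- rbind(truth, data.frame(
      probe_id = probe_id[ct_idx], effect = "celltype",
      direction = ifelse(sgn > 0, "more_methylated", "less_methylated"),
      magnitude = cfg$celltype_effect, stringsAsFactors = FALSE))
  }
  if (length(ph_idx)) {
    sgn <- ifelse(is_meth[ph_idx], -1, 1)
    aff <- sheet$cell_type == cfg$phenotype_cell_type &
      sheet$phenotype %in% cfg$phenotype_affected
    if (any(aff))
      M[ph_idx, aff] <- M[ph_idx, aff] + sgn * cfg$phenotype_effect
    truth <- rbind(truth, data.frame(
      probe_id = probe_id[ph_idx], effect = "phenotype",
      direction = ifelse(sgn > 0, "more_methylated", "less_methylated"),
      magnitude = cfg$phenotype_effect, stringsAsFactors = FALSE))
  }

  ## --- batch displacement (M scale, fixed random unit direction) ---------
  set.seed(seeds[["batch"]])
  if (cfg$n_batches > 1L && cfg$batch_shift != 0) {
    u <- stats::rnorm(np)
    u <- u / sqrt(sum(u^2))
    blev <- paste0("batch", seq_len(cfg$n_batches))
    shift_of <- cfg$batch_shift * (match(sheet$batch, blev) - 1L)
    M <- M + outer(u, shift_of)
  }

  ## --- noise -------------------------------------------------------------
  set.seed(seeds[["noise"]])
  M <- M + matrix(stats::rnorm(np * ns, 0, cfg$noise_sd), np, ns)

  ## --- back-transform to intensities -------------------------------------
  set.seed(seeds[["intensity"]])
  beta <- 2^M / (2^M + 1)
  bright <- 2^matrix(stats::rnorm(np * ns, 0, cfg$intensity_noise_sd_log2),
                     np, ns)
  cy5 <- cfg$intensity_scale * beta * bright
  cy3 <- cfg$intensity_scale * (1 - beta) * bright
  dimnames(cy5) <- dimnames(cy3) <- dimnames(M)

  ## --- detection p-values -------------------------------------------------
  set.seed(seeds[["detection"]])
  failed <- stats::runif(np * ns) < cfg$frac_detection_failed
  dp <- ifelse(failed, stats::runif(np * ns, 0.05 + 1e-6, 1),
               stats::runif(np * ns, 0, 0.05))
  dp <- matrix(dp, np, ns, dimnames = dimnames(M))

  list(dataset = intensity_dataset(man, sheet, cy5, cy3, dp),
       truth = truth, config = cfg)
}

#' Recall and false-discovery proportion of a call set against truth
#'
#' @param calls character vector of called probe IDs.
#' @param truth character vector of true effect-carrying probe IDs, or a
#'   truth data.frame from [simulate_dataset()] (its `probe_id` column is
#'   used).
#' @return Named numeric vector `c(recall=, fdp=)`:
#'   `recall = |calls .. truth| / |truth|` and
#'   `fdp = |calls \\ truth| / max(|calls|, 1)`.
#' @export
truth_recall <- function(calls, truth) {
  if (is.data.frame(truth)) truth <- truth$probe_id
  calls <- unique(as.character(calls))
  truth <- unique(as.character(truth))
  recall <- if (length(truth)) length(intersect(calls, truth)) / length(truth)
            else 0
  fdp <- length(setdiff(calls, truth)) / max(length(calls), 1L)
  c(recall = recall, fdp = fdp)
}
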