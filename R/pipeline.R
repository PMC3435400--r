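#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis.  The default
#' comparison plan (built at run time from the sample sheet) mirrors the
#' matched two-tissue design: first atopic-asthmatic vs non-atopic-
#' asthmatic within each cell type (whose outcome decides whether the two
#' asthma subgroups are merged, see [grouped_asthma_check()]), then AEC vs
#' PBMC over all subjects and within each phenotype, then every phenotype
#' pair within each cell type.  Comparisons whose groups have fewer than
#' two samples are skipped (and logged).
#'
#' @param detection_alpha,max_fail_frac probe-filter parameters, see
#'   [filter_probes()].
#' @param knn_k neighbours for [knn_impute()].
#' @param impute_stage `"post"` (default: impute on the M-value scale
#'   after batch adjustment, where KNN distances are best behaved) or
#'   `"pre"` (impute the raw channel intensities before correction).
#' @param batch_correct apply [dwd_batch_adjust()] when more than one
#'   batch is present.
#' @param dwd_penalty optional DWD penalty (`NULL` = heuristic).
#' @param paired use the paired t-test for cell-type comparisons
#'   (samples are subject-matched); phenotype comparisons are always
#'   unpaired (different subjects).
#' @param q_threshold,d_threshold dual calling thresholds, see
#'   [call_differential()].
#' @param comparisons optional explicit comparison plan: a list of
#'   `list(name=, stratum=, variable=, levels=)` entries where `stratum`
#'   is a named list of sample-sheet column = kept values; `NULL` uses the
#'   default plan.
#' @param annotation optional gene-to-function annotation data.frame
#'   (columns `gene`, `function_label`) enabling enrichment of the core
#'   signature.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(detection_alpha = 0.05, max_fail_frac = 0.10,
                            knn_k = 10,
                            impute_stage = c("post", "pre"),
                            batch_correct = TRUE, dwd_penalty = NULL,
                            paired = FALSE,
                            q_threshold = 0.05, d_threshold = 2,
                            comparisons = NULL, annotation = NULL) {
  impute_stage <- match.arg(impute_stage)
  if (q_threshold <= 0 || q_threshold > 1)
    stop("q_threshold must lie in (0, 1]", call. = FALSE)
  if (d_threshold < 0) stop("d_threshold must be >= 0", call. = FALSE)
  if (!is.null(comparisons)) {
    nms <- vapply(comparisons, `[[`, character(1), "name")
    if (anyDuplicated(nms)) stop("comparison names must be unique",
                                 call. = FALSE)
  }
  structure(list(detection_alpha = detection_alpha,
                 max_fail_frac = max_fail_frac, knn_k = knn_k,
                 impute_stage = impute_stage,
                 batch_correct = batch_correct, dwd_penalty = dwd_penalty,
                 paired = paired, q_threshold = q_threshold,
                 d_threshold = d_threshold, comparisons = comparisons,
                 annotation = annotation),
            class = "pipeline_config")
}

#' Decide whether the two asthma subgroups can be merged
#'
#' Returns `TRUE` — merge atopic-asthmatic and non-atopic-asthmatic into a
#' single asthmatic group — iff zero probes are called in *both* of the
#' within-cell-type subgroup comparisons.
#'
#' @param res_aec,res_pbmc `differential_result`s of the atopic-asthmatic
#'   vs non-atopic-asthmatic comparison within AECs and within PBMCs.
#' @return logical merge decision.
#' @export
grouped_asthma_check <- function(res_aec, res_pbmc) {
  sum(res_aec$called) == 0L && sum(res_pbmc$called) == 0L
}

select_samples <- function(sheet, stratum) {
  keep <- rep(TRUE, nrow(sheet))
  for (var in names(stratum))
    keep <- keep & sheet[[var]] %in% stratum[[var]]
  sheet$sample_id[keep]
}

# Effective phenotype labels after an asthma-subgroup merge.
effective_phenotype <- function(sheet, merged) {
  ph <- sheet$phenotype
  if (merged)
    ph[ph %in% c("atopic_asthmatic", "nonatopic_asthmatic")] <- "asthmatic"
  ph
}

default_comparison_plan <- function(sheet, merged) {
  ph <- effective_phenotype(sheet, merged)
  phen_levels <- intersect(c("healthy", "atopic", "asthmatic",
                             "atopic_asthmatic", "nonatopic_asthmatic"),
                           unique(ph))
  plan <- list()
  plan[[length(plan) + 1L]] <- list(name = "celltype_all", stratum = list(),
                                    variable = "cell_type",
                                    levels = c("AEC", "PBMC"))
  for (p in phen_levels)
    plan[[length(plan) + 1L]] <- list(
      name = paste0("celltype_", p),
      stratum = list(phenotype_eff = p),
      variable = "cell_type", levels = c("AEC", "PBMC"))
  if (length(phen_levels) >= 2L)
    for (ct in intersect(c("AEC", "PBMC"), unique(sheet$cell_type))) {
      pairs <- utils::combn(phen_levels, 2L)
      for (k in seq_len(ncol(pairs)))
        plan[[length(plan) + 1L]] <- list(
          name = paste0(tolower(ct), "_", pairs[1L, k], "_vs_",
                        pairs[2L, k]),
          stratum = list(cell_type = ct),
          variable = "phenotype_eff", levels = pairs[, k])
    }
  plan
}

run_comparison <- function(Z, sheet, cmp, cfg) {
  sheet2 <- as.data.frame(unclass(sheet))
  sheet2$phenotype_eff <- sheet2$phenotype_eff %||% sheet2$phenotype
  keep <- select_samples(sheet2, cmp$stratum)
  sub <- sheet2[match(keep, sheet2$sample_id), , drop = FALSE]
  grp_var <- sub[[cmp$variable]]
  sub <- sub[grp_var %in% cmp$levels, , drop = FALSE]
  grp <- factor(sub[[cmp$variable]], levels = cmp$levels)
  if (any(table(grp) < 2L)) return(NULL)
  paired <- cfg$paired && cmp$variable == "cell_type"
  call_differential(Z$values[, sub$sample_id, drop = FALSE],
                    grp,
                    q_threshold = cfg$q_threshold,
                    d_threshold = cfg$d_threshold,
                    paired = paired, subject = sub$subject_id,
                    manifest = attr(Z, "manifest"),
                    comparison = cmp$name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full methylation-signature pipeline
#'
#' Executes, in order: probe filtering, (pre-stage imputation,)
#' background correction, colour-bias correction, M-value computation,
#' DWD batch adjustment, (post-stage imputation,) per-sample z-scoring,
#' the comparison plan with dual-threshold differential calling, signature
#' construction, three-way Venn decomposition of the per-phenotype
#' cell-type signatures, and (optionally) functional enrichment of the
#' core signature.  Deterministic: a re-run on the same inputs writes
#' bit-identical outputs.
#'
#' @param ds an [intensity_dataset()] (e.g. from [read_dataset()] or
#'   [simulate_dataset()]).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; when given, every
#'   intermediate matrix, the filter report, all per-comparison result
#'   TSVs, signature and Venn tables, a plain-text log and a
#'   machine-readable JSON run manifest (config echo plus MD5 provenance
#'   hashes) are written there.
#' @return Object of class `methsig_run`: list with `filter_report`,
#'   `m_values`, `z_scores` (both `methylation_matrix`), `results` (named
#'   list of `differential_result`), `signatures`, `venn`, `enrichment`,
#'   `asthma_merged` (logical or NA when the subgroup comparisons were not
#'   feasible), `skipped_comparisons`, `config` and `out_dir`.
#' @export
run_pipeline <- function(ds, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(ds, "intensity_dataset"),
            inherits(config, "pipeline_config"))
  log_lines <- character()
  note <- function(stage, msg) {
    line <- sprintf("%s\t%s\t%s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    stage, msg)
    log_lines <<- c(log_lines, line)
  }
  fail <- function(stage, e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)

  ## filter ----------------------------------------------------------------
  flt <- tryCatch(filter_probes(ds, config$detection_alpha,
                                config$max_fail_frac),
                  error = function(e) fail("filter", e))
  note("filter", sprintf("retained %d of %d probes",
                         flt$report$n_retained, flt$report$n_input))
  ds <- flt$dataset

  ## pre-stage imputation on raw intensities -------------------------------
  mask <- ds$detection_p > config$detection_alpha
  if (config$impute_stage == "pre" && any(mask)) {
    ds$cy5 <- tryCatch(knn_impute(ds$cy5, mask, k = config$knn_k),
                       error = function(e) fail("impute", e))
    ds$cy3 <- tryCatch(knn_impute(ds$cy3, mask, k = config$knn_k),
                       error = function(e) fail("impute", e))
    note("impute", sprintf("imputed %d intensity entries (pre stage)",
                           sum(mask)))
  }

  ## intensity corrections -------------------------------------------------
  ds <- tryCatch(correct_color_bias(correct_background(ds)),
                 error = function(e) fail("normalize", e))
  note("normalize", "background + colour-bias corrected")

  ## M-values --------------------------------------------------------------
  m <- tryCatch(compute_m_values(ds), error = function(e) fail("mvalues", e))

  ## batch adjustment ------------------------------------------------------
  n_batches <- length(unique(ds$samples$batch))
  if (config$batch_correct && n_batches > 1L) {
    m <- tryCatch(dwd_batch_adjust(m, ds$samples$batch,
                                   penalty_C = config$dwd_penalty),
                  error = function(e) fail("batch", e))
    note("batch", sprintf("DWD-adjusted %d batches", n_batches))
  } else note("batch", "skipped (single batch or disabled)")

  ## post-stage imputation on M-values -------------------------------------
  if (config$impute_stage == "post" && any(mask)) {
    m <- tryCatch(impute_methylation(m, mask, k = config$knn_k),
                  error = function(e) fail("impute", e))
    note("impute", sprintf("imputed %d M-value entries (post stage)",
                           sum(mask)))
  } else if (config$impute_stage == "pre") {
    m$imputed_mask <- m$imputed_mask | mask
  }

  ## z-scoring -------------------------------------------------------------
  z <- tryCatch(zscore_standardize(m), error = function(e) fail("zscore", e))
  attr(z, "manifest") <- ds$manifest
  note("zscore", "per-sample z-score standardisation")

  ## asthma subgroup check -------------------------------------------------
  sheet <- as.data.frame(unclass(ds$samples))
  merged <- NA
  subgroup_res <- list()
  has_subtypes <- all(c("atopic_asthmatic", "nonatopic_asthmatic") %in%
                        sheet$phenotype)
  if (has_subtypes) {
    sheet$phenotype_eff <- sheet$phenotype
    for (ct in c("AEC", "PBMC")) {
      cmp <- list(name = paste0(tolower(ct), "_asthma_subtypes"),
                  stratum = list(cell_type = ct), variable = "phenotype",
                  levels = c("atopic_asthmatic", "nonatopic_asthmatic"))
      subgroup_res[[cmp$name]] <- run_comparison(z, sheet, cmp, config)
    }
    if (!any(vapply(subgroup_res, is.null, logical(1))) &&
        length(subgroup_res) == 2L) {
      merged <- grouped_asthma_check(subgroup_res[[1L]], subgroup_res[[2L]])
      note("asthma_check",
           sprintf("merge asthma subgroups: %s", merged))
    } else note("asthma_check", "subgroup comparison not feasible")
  }
  merge_now <- isTRUE(merged) || !has_subtypes

  ## comparison plan --------------------------------------------------------
  sheet$phenotype_eff <- effective_phenotype(ds$samples, merge_now)
  plan <- config$comparisons %||% default_comparison_plan(ds$samples,
                                                          merge_now)
  results <- subgroup_res[!vapply(subgroup_res, is.null, logical(1))]
  skipped <- character()
  for (cmp in plan) {
    r <- run_comparison(z, sheet, cmp, config)
    if (is.null(r)) {
      skipped <- c(skipped, cmp$name)
      note("compare", sprintf("%s skipped (< 2 samples in a group)",
                              cmp$name))
    } else {
      results[[cmp$name]] <- r
      note("compare", sprintf("%s: %d/%d called", cmp$name, sum(r$called),
                              nrow(r)))
    }
  }

  ## signatures + Venn ------------------------------------------------------
  signatures <- lapply(names(results), function(nm)
    build_signature(results[[nm]], nm, manifest = ds$manifest))
  names(signatures) <- names(results)
  venn <- NULL
  venn_names <- paste0("celltype_", c("healthy", "atopic", "asthmatic"))
  if (all(venn_names %in% names(signatures))) {
    venn <- venn_decompose(signatures[venn_names])
    note("venn", sprintf("core %d; unique %s", length(venn$core),
                         paste(venn$counts$unique, collapse = "/")))
  }

  ## enrichment -------------------------------------------------------------
  enrichment <- NULL
  if (!is.null(config$annotation) && !is.null(venn) &&
      length(venn$core) > 0L) {
    core_sig <- build_signature(
      data.frame(probe_id = venn$core, z_diff = 1, called = TRUE,
                 stringsAsFactors = FALSE), "core", manifest = ds$manifest)
    enrichment <- fisher_enrichment(core_sig, config$annotation,
                                    unique(ds$manifest$gene))
    note("enrichment", sprintf("%d functions tested", nrow(enrichment)))
  }

  run <- structure(list(filter_report = flt$report, m_values = m,
                        z_scores = z, results = results,
                        signatures = signatures, venn = venn,
                        enrichment = enrichment, asthma_merged = merged,
                        skipped_comparisons = skipped, config = config,
                        out_dir = out_dir, log = log_lines),
                   class = "methsig_run")
  if (!is.null(out_dir)) write_run(run, ds, out_dir)
  run
}

# Write every artefact of a pipeline run to `dir`.
write_run <- function(run, ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_table(as.data.frame(run$filter_report),
              file.path(dir, "filter_report.tsv"))
  write_matrix(run$m_values, file.path(dir, "M.tsv"))
  write_matrix(run$z_scores, file.path(dir, "Z.tsv"))
  for (nm in names(run$results)) {
    res <- as.data.frame(run$results[[nm]])
    write_table(res, file.path(dir, paste0("results_", nm, ".tsv")))
    write_table(volcano_data(run$results[[nm]]),
                file.path(dir, paste0("volcano_", nm, ".tsv")))
  }
  for (nm in names(run$signatures))
    write_table(run$signatures[[nm]]$table,
                file.path(dir, paste0("signature_", nm, ".tsv")))
  if (!is.null(run$venn))
    write_table(run$venn$counts, file.path(dir, "venn_counts.tsv"))
  if (!is.null(run$enrichment))
    write_table(as.data.frame(run$enrichment),
                file.path(dir, "enrichment.tsv"))
  writeLines(run$log, file.path(dir, "run.log"))

  cfg <- run$config
  manifest <- list(
    package = "methsig",
    version = as.character(utils::packageVersion("methsig")),
    config = cfg[setdiff(names(cfg), "annotation")],
    asthma_merged = run$asthma_merged,
    n_probes_analyzed = nrow(run$z_scores$values),
    n_samples = ncol(run$z_scores$values),
    input_hash = unname(input_hash(ds)))
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}

# MD5 provenance hash of the dataset content (written to a temp file so
# the hash covers exactly what write_dataset would persist).
input_hash <- function(ds) {
  td <- tempfile("methsig_hash_")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  write_dataset(ds, td)
  paste(tools::md5sum(sort(list.files(td, full.names = TRUE))),
        collapse = "")
}

#' @export
print.methsig_run <- function(x, ...) {
  cat("Methylation-signature pipeline run\n")
  print(x$filter_report)
  if (!is.na(x$asthma_merged))
    cat(sprintf("  asthma subgroups merged: %s\n", x$asthma_merged))
  cat(sprintf("  comparisons run: %d (skipped: %d)\n", length(x$results),
              length(x$skipped_comparisons)))
  for (nm in names(x$results))
    cat(sprintf("    %-28s %4d called\n", nm, sum(x$results[[nm]]$called)))
  if (!is.null(x$venn))
    cat(sprintf("  Venn core: %d CpGs; unique per set: %s\n",
                length(x$venn$core),
                paste(x$venn$counts$unique, collapse = "/")))
  invisible(x)
}
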