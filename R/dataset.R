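#' Construct a probe manifest
#'
#' The manifest describes a CpG panel: one row per probe with its opaque
#' `probe_id`, its panel `target_id` (see [parse_target_id()]), the
#' chromosome, and whether the probe sequence contains a known SNP.  The
#' target ID is parsed on construction so the derived columns `gene`,
#' `region_class`, `tss_distance` and `strand` are always available.
#'
#' @param df data.frame with columns `probe_id`, `target_id`, `chromosome`
#'   and `snp_in_probe` (logical or 0/1).
#' @return The validated data.frame, augmented with the parsed target-ID
#'   fields, of class `probe_manifest`.
#' @export
probe_manifest <- function(df) {
  req <- c("probe_id", "target_id", "chromosome", "snp_in_probe")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("manifest is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (anyDuplicated(df$probe_id)) {
    dup <- unique(df$probe_id[duplicated(df$probe_id)])
    stop("duplicate probe_id in manifest: ",
         paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
  }
  ok_chr <- c(as.character(1:22), "X", "Y")
  bad <- setdiff(unique(as.character(df$chromosome)), ok_chr)
  if (length(bad))
    stop("unknown chromosome label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  df$chromosome <- as.character(df$chromosome)
  df$snp_in_probe <- as.logical(as.integer(df$snp_in_probe))
  parsed <- parse_target_id(df$target_id)
  df$gene <- parsed$gene
  df$region_class <- parsed$region_class
  df$tss_distance <- parsed$tss_distance
  df$strand <- parsed$strand
  rownames(df) <- NULL
  class(df) <- c("probe_manifest", "data.frame")
  df
}

#' Construct a sample sheet
#'
#' One row per array sample.  The design is a matched two-tissue study:
#' each subject contributes one airway-epithelial-cell (`AEC`) and one
#' peripheral-blood-mononuclear-cell (`PBMC`) sample, and subjects fall
#' into one of four phenotype groups (`healthy`, `atopic`,
#' `atopic_asthmatic`, `nonatopic_asthmatic`).
#'
#' @param df data.frame with columns `sample_id`, `subject_id`,
#'   `cell_type`, `phenotype`, `batch`, `sex` and `age`.
#' @return Validated data.frame of class `sample_sheet`.
#' @export
sample_sheet <- function(df) {
  req <- c("sample_id", "subject_id", "cell_type", "phenotype", "batch",
           "sex", "age")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("sample sheet is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in sample sheet", call. = FALSE)
  if (anyDuplicated(paste(df$subject_id, df$cell_type, sep = "\r")))
    stop("duplicate (subject_id, cell_type) pair in sample sheet",
         call. = FALSE)
  if (!all(df$cell_type %in% c("AEC", "PBMC")))
    stop("cell_type must be 'AEC' or 'PBMC'", call. = FALSE)
  if (!all(df$phenotype %in% phenotype_levels()))
    stop("phenotype must be one of: ",
         paste(phenotype_levels(), collapse = ", "), call. = FALSE)
  if (!all(df$sex %in% c("M", "F", "unknown")))
    stop("sex must be 'M', 'F' or 'unknown'", call. = FALSE)
  df$age <- as.numeric(df$age)
  if (anyNA(df$age) || any(df$age < 0))
    stop("age must be a non-negative number of years", call. = FALSE)
  df$batch <- as.character(df$batch)
  rownames(df) <- NULL
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Closed phenotype vocabulary
#'
#' @return character vector of the four recognised phenotype labels.
#' @export
phenotype_levels <- function() {
  c("healthy", "atopic", "atopic_asthmatic", "nonatopic_asthmatic")
}

#' Construct an intensity dataset
#'
#' Container for raw two-colour bead-array data: per-probe, per-sample Cy5
#' (methylated-channel) and Cy3 (unmethylated-channel) intensities and
#' detection p-values, tied to a [probe_manifest()] and a [sample_sheet()].
#' All three matrices are addressed by probe and sample ID (dimnames), never
#' by position, so filtering is auditable.
#'
#' @param manifest a `probe_manifest`.
#' @param samples a `sample_sheet`.
#' @param cy5,cy3 probe x sample numeric matrices of non-negative
#'   intensities (arbitrary units) with rownames = probe IDs and
#'   colnames = sample IDs.
#' @param detection_p probe x sample matrix of detection p-values in
#'   \[0,1\]; a value > 0.05 conventionally marks a failed measurement.
#' @return Object of class `intensity_dataset`: a list with the five
#'   fields above.
#' @export
intensity_dataset <- function(manifest, samples, cy5, cy3, detection_p) {
  if (!inherits(manifest, "probe_manifest")) manifest <- probe_manifest(manifest)
  if (!inherits(samples, "sample_sheet")) samples <- sample_sheet(samples)
  mats <- list(cy5 = cy5, cy3 = cy3, detection_p = detection_p)
  for (nm in names(mats)) {
    m <- mats[[nm]]
    if (!is.matrix(m) || !is.numeric(m))
      stop("'", nm, "' must be a numeric matrix", call. = FALSE)
    if (!identical(rownames(m), manifest$probe_id))
      stop("'", nm, "' rownames do not match manifest probe IDs (order matters)",
           call. = FALSE)
    if (!identical(colnames(m), samples$sample_id))
      stop("'", nm, "' colnames do not match sample sheet sample IDs",
           call. = FALSE)
    if (anyNA(m)) stop("'", nm, "' contains NA", call. = FALSE)
  }
  if (any(cy5 < 0) || any(cy3 < 0))
    stop("intensities must be non-negative", call. = FALSE)
  if (any(detection_p < 0 | detection_p > 1))
    stop("detection p-values must lie in [0, 1]", call. = FALSE)
  structure(list(manifest = manifest, samples = samples,
                 cy5 = cy5, cy3 = cy3, detection_p = detection_p),
            class = "intensity_dataset")
}

#' @export
print.intensity_dataset <- function(x, ...) {
  cat("Two-colour methylation intensity dataset\n")
  cat(sprintf("  probes : %d (%d genes)\n", nrow(x$manifest),
              length(unique(x$manifest$gene))))
  cat(sprintf("  samples: %d (%d subjects; cell types: %s)\n",
              nrow(x$samples), length(unique(x$samples$subject_id)),
              paste(sort(unique(x$samples$cell_type)), collapse = ", ")))
  cat(sprintf("  detection-failed entries (p > 0.05): %.3f%%\n",
              100 * mean(x$detection_p > 0.05)))
  invisible(x)
}

#' @export
dim.intensity_dataset <- function(x) dim(x$cy5)

#' Subset an intensity dataset by probe and/or sample ID
#'
#' @param ds an `intensity_dataset`.
#' @param probes character vector of probe IDs to keep (default: all).
#' @param samples character vector of sample IDs to keep (default: all).
#' @return The subsetted `intensity_dataset`.
#' @export
subset_dataset <- function(ds, probes = NULL, samples = NULL) {
  stopifnot(inherits(ds, "intensity_dataset"))
  pid <- if (is.null(probes)) ds$manifest$probe_id else probes
  sid <- if (is.null(samples)) ds$samples$sample_id else samples
  if (!all(pid %in% ds$manifest$probe_id))
    stop("unknown probe ID(s) in subset", call. = FALSE)
  if (!all(sid %in% ds$samples$sample_id))
    stop("unknown sample ID(s) in subset", call. = FALSE)
  man <- ds$manifest[match(pid, ds$manifest$probe_id), , drop = FALSE]
  rownames(man) <- NULL
  class(man) <- c("probe_manifest", "data.frame")
  smp <- ds$samples[match(sid, ds$samples$sample_id), , drop = FALSE]
  rownames(smp) <- NULL
  class(smp) <- c("sample_sheet", "data.frame")
  structure(list(manifest = man, samples = smp,
                 cy5 = ds$cy5[pid, sid, drop = FALSE],
                 cy3 = ds$cy3[pid, sid, drop = FALSE],
                 detection_p = ds$detection_p[pid, sid, drop = FALSE]),
            class = "intensity_dataset")
}

#' Construct a methylation matrix
#'
#' Probe x sample matrix of M-values (`scale = "M"`) or of per-sample
#' z-scores (`scale = "Z"`), with a logical mask recording which entries
#' were imputed because the underlying measurement failed detection.
#'
#' @param values numeric probe x sample matrix with dimnames.
#' @param scale `"M"` or `"Z"`.
#' @param imputed_mask logical matrix of the same shape; `TRUE` marks
#'   imputed (originally detection-failed) entries.  Defaults to all
#'   `FALSE`.
#' @return Object of class `methylation_matrix`.
#' @export
methylation_matrix <- function(values, scale = c("M", "Z"),
                               imputed_mask = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry probe and sample dimnames", call. = FALSE)
  if (is.null(imputed_mask))
    imputed_mask <- matrix(FALSE, nrow(values), ncol(values),
                           dimnames = dimnames(values))
  if (!identical(dim(imputed_mask), dim(values)))
    stop("'imputed_mask' shape must match 'values'", call. = FALSE)
  if (scale == "Z") {
    mu <- colMeans(values)
    sd <- apply(values, 2L, stats::sd)
    if (any(abs(mu) > 1e-8) || any(abs(sd - 1) > 1e-8))
      stop("Z-scale matrix must have column mean 0 and sd 1 (tol 1e-8)",
           call. = FALSE)
  }
  structure(list(values = values, scale = scale, imputed_mask = imputed_mask),
            class = "methylation_matrix")
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat(sprintf("Methylation matrix (%s scale): %d probes x %d samples; %d imputed entries\n",
              x$scale, nrow(x$values), ncol(x$values), sum(x$imputed_mask)))
  invisible(x)
}

#' @export
dim.methylation_matrix <- function(x) dim(x$values)
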