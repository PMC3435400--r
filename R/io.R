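# Tabular readers/writers.  All files are UTF-8, tab-separated, '.' decimal.
# The intensity file is long-form (probe_id, sample_id, cy5, cy3,
# detection_p); matrices are reconstructed against the manifest / sample
# sheet axes so probe and sample order is always taken from those files.

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path))
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("%s file %s is missing columns: %s", what, path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  df
}

#' Read an intensity dataset from tab-separated files
#'
#' @param manifest_path TSV with columns `probe_id`, `target_id`,
#'   `chromosome`, `snp_in_probe` (0/1).
#' @param intensity_path long-form TSV with columns `probe_id`,
#'   `sample_id`, `cy5`, `cy3`, `detection_p`.  A missing detection
#'   p-value is treated as 1 (certain failure), which is conservative for
#'   the > 0.05 failure rule.
#' @param samplesheet_path TSV with columns `sample_id`, `subject_id`,
#'   `cell_type`, `phenotype`, `batch`, `sex`, `age`.
#' @return An [intensity_dataset()].  Every (probe, sample) pair present in
#'   the manifest and sample sheet must appear exactly once in the
#'   intensity file; samples in the intensity file that are absent from the
#'   sheet (or vice versa) are an error.
#' @export
read_dataset <- function(manifest_path, intensity_path, samplesheet_path) {
  man <- probe_manifest(read_tsv_checked(
    manifest_path, c("probe_id", "target_id", "chromosome", "snp_in_probe"),
    "manifest"))
  sheet <- sample_sheet(read_tsv_checked(
    samplesheet_path,
    c("sample_id", "subject_id", "cell_type", "phenotype", "batch", "sex",
      "age"), "sample sheet"))
  long <- read_tsv_checked(
    intensity_path, c("probe_id", "sample_id", "cy5", "cy3", "detection_p"),
    "intensity")

  extra_s <- setdiff(unique(long$sample_id), sheet$sample_id)
  if (length(extra_s))
    stop("intensity file contains samples absent from the sample sheet: ",
         paste(utils::head(extra_s, 5L), collapse = ", "), call. = FALSE)
  extra_p <- setdiff(unique(long$probe_id), man$probe_id)
  if (length(extra_p))
    stop("intensity file contains probes absent from the manifest: ",
         paste(utils::head(extra_p, 5L), collapse = ", "), call. = FALSE)

  for (col in c("cy5", "cy3")) {
    v <- suppressWarnings(as.numeric(long[[col]]))
    if (anyNA(v))
      stop("non-numeric value in intensity column '", col, "'", call. = FALSE)
    long[[col]] <- v
  }
  dp <- suppressWarnings(as.numeric(long$detection_p))
  dp[is.na(long$detection_p)] <- 1          # missing detection p => failed
  if (anyNA(dp))
    stop("non-numeric value in intensity column 'detection_p'", call. = FALSE)
  long$detection_p <- dp

  key <- paste(long$probe_id, long$sample_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (probe_id, sample_id) row in intensity file",
         call. = FALSE)

  np <- nrow(man); ns <- nrow(sheet)
  dn <- list(man$probe_id, sheet$sample_id)
  idx <- cbind(match(long$probe_id, man$probe_id),
               match(long$sample_id, sheet$sample_id))
  fill <- function(col) {
    m <- matrix(NA_real_, np, ns, dimnames = dn)
    m[idx] <- long[[col]]
    if (anyNA(m)) {
      bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
      stop(sprintf("intensity file has no row for probe '%s', sample '%s'",
                   dn[[1L]][bad[1L]], dn[[2L]][bad[2L]]), call. = FALSE)
    }
    m
  }
  intensity_dataset(man, sheet, fill("cy5"), fill("cy3"), fill("detection_p"))
}

#' Write a data.frame as a deterministic TSV
#'
#' UTF-8, tab-separated, '.' decimal, no quoting, no row names; column
#' order as given.  Writing the same object twice yields bit-identical
#' files.
#'
#' @param df a data.frame (a header-only file is written when it has zero
#'   rows).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df))
    if (is.numeric(df[[j]])) df[[j]] <- format(df[[j]], digits = 15,
                                               trim = TRUE, scientific = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write an intensity dataset to a directory of TSV files
#'
#' Writes `manifest.tsv`, `intensities.tsv` (long form, probes varying
#' slowest) and `samplesheet.tsv` in the formats read by [read_dataset()].
#' The write is deterministic: a second write of the same dataset is
#' bit-identical.
#'
#' @param ds an `intensity_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "intensity_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_table(ds$manifest[, c("probe_id", "target_id", "chromosome",
                              "snp_in_probe")],
              file.path(dir, "manifest.tsv"))
  write_table(as.data.frame(unclass(ds$samples))[
    , c("sample_id", "subject_id", "cell_type", "phenotype", "batch", "sex",
        "age")], file.path(dir, "samplesheet.tsv"))
  long <- data.frame(
    probe_id = rep(ds$manifest$probe_id, times = ncol(ds$cy5)),
    sample_id = rep(ds$samples$sample_id, each = nrow(ds$cy5)),
    cy5 = as.vector(ds$cy5),
    cy3 = as.vector(ds$cy3),
    detection_p = as.vector(ds$detection_p),
    stringsAsFactors = FALSE)
  long <- long[order(match(long$probe_id, ds$manifest$probe_id),
                     match(long$sample_id, ds$samples$sample_id)), ]
  write_table(long, file.path(dir, "intensities.tsv"))
  invisible(dir)
}

#' Write a methylation matrix as a wide TSV
#'
#' First column `probe_id`, one column per sample.
#'
#' @param m a `methylation_matrix` or plain probe x sample matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  v <- if (inherits(m, "methylation_matrix")) m$values else m
  df <- data.frame(probe_id = rownames(v), as.data.frame(v,
                   check.names = FALSE), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table(df, path)
}

#' Read a wide methylation-matrix TSV written by [write_matrix()]
#'
#' @param path input path.
#' @param scale `"M"` or `"Z"` scale tag for the result.
#' @return A `methylation_matrix`.
#' @export
read_matrix <- function(path, scale = "M") {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  v <- as.matrix(df[, -1L, drop = FALSE])
  rownames(v) <- df[[1L]]
  methylation_matrix(v, scale = scale)
}
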