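#' Filter panel probes before analysis
#'
#' Removes probes in three sequential, single-counted categories:
#' \enumerate{
#'   \item all probes on the X chromosome (avoids sex bias),
#'   \item probes whose sequence contains a known SNP,
#'   \item probes whose detection p-value exceeds `detection_alpha` in
#'     strictly more than `max_fail_frac` of samples.
#' }
#' A probe falling in several categories is counted once, in the order
#' above, so the report always reconciles:
#' `n_input = n_removed_x + n_removed_snp + n_removed_detection +
#' n_retained`.
#'
#' @param ds an [intensity_dataset()].
#' @param detection_alpha detection p-value above which a measurement
#'   counts as failed (default 0.05).
#' @param max_fail_frac a probe is dropped when its failed fraction is
#'   strictly greater than this (default 0.10, i.e. "more than 10% of
#'   samples").
#' @return list with `dataset` (the filtered `intensity_dataset`) and
#'   `report` (a `filter_report`: counts plus per-category removed probe
#'   IDs).  An empty retained set is an error.
#' @export
filter_probes <- function(ds, detection_alpha = 0.05, max_fail_frac = 0.10) {
  stopifnot(inherits(ds, "intensity_dataset"))
  man <- ds$manifest
  remaining <- man$probe_id

  rm_x <- man$probe_id[man$chromosome == "X"]
  remaining <- setdiff(remaining, rm_x)

  rm_snp <- intersect(man$probe_id[man$snp_in_probe], remaining)
  remaining <- setdiff(remaining, rm_snp)

  fail_frac <- rowMeans(ds$detection_p[remaining, , drop = FALSE] >
                          detection_alpha)
  rm_det <- remaining[fail_frac > max_fail_frac]   # strict inequality
  remaining <- setdiff(remaining, rm_det)

  if (length(remaining) == 0L)
    stop("probe filtering removed every probe; nothing to analyze",
         call. = FALSE)

  report <- structure(list(
    n_input = nrow(man),
    n_removed_x = length(rm_x),
    n_removed_snp = length(rm_snp),
    n_removed_detection = length(rm_det),
    n_retained = length(remaining),
    removed_ids = list(x_chromosome = rm_x, snp_in_probe = rm_snp,
                       detection = rm_det),
    detection_alpha = detection_alpha,
    max_fail_frac = max_fail_frac), class = "filter_report")
  list(dataset = subset_dataset(ds, probes = remaining), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Probe filter report\n")
  cat(sprintf("  input probes        : %d\n", x$n_input))
  cat(sprintf("  removed X chromosome: %d\n", x$n_removed_x))
  cat(sprintf("  removed SNP-in-probe: %d\n", x$n_removed_snp))
  cat(sprintf("  removed detection   : %d (p > %g in > %g%% of samples)\n",
              x$n_removed_detection, x$detection_alpha,
              100 * x$max_fail_frac))
  cat(sprintf("  retained            : %d\n", x$n_retained))
  invisible(x)
}

#' @export
as.data.frame.filter_report <- function(x, ...) {
  data.frame(category = c("input", "x_chromosome", "snp_in_probe",
                          "detection", "retained"),
             n = c(x$n_input, x$n_removed_x, x$n_removed_snp,
                   x$n_removed_detection, x$n_retained),
             stringsAsFactors = FALSE)
}

#' K-nearest-neighbour imputation of masked matrix entries
#'
#' For each masked entry (target probe i, sample j): candidate neighbour
#' probes are those observed in sample j; the distance to each candidate
#' is the Euclidean distance over samples where both probes are observed;
#' the `k` nearest candidates are combined by inverse-distance weighting of
#' their values in sample j.  A candidate at distance zero (duplicate row)
#' is copied directly (zero-distance neighbours share the weight equally).
#' A target probe with no co-observed samples against any candidate falls
#' back to its own observed mean.
#'
#' @param values numeric probe x sample matrix.
#' @param mask logical matrix of the same shape; `TRUE` marks entries to
#'   impute.  Observed entries are never modified.
#' @param k number of neighbours (default 10).
#' @return The completed matrix.
#' @export
knn_impute <- function(values, mask, k = 10) {
  if (!is.matrix(values) || !identical(dim(mask), dim(values)))
    stop("'values' and 'mask' must be matrices of identical shape",
         call. = FALSE)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  fully_masked <- rowSums(!mask) == 0L
  if (any(fully_masked))
    stop("fully-masked probe(s): ",
         paste(utils::head(rownames(values)[fully_masked], 5L),
               collapse = ", "), call. = FALSE)
  if (!any(mask)) return(values)

  out <- values
  obs <- !mask
  targets <- which(rowSums(mask) > 0L)
  for (i in targets) {
    for (j in which(mask[i, ])) {
      cand <- which(obs[, j])
      cand <- cand[cand != i]
      if (length(cand) == 0L) {
        out[i, j] <- mean(values[i, obs[i, ]])
        next
      }
      # squared distance over co-observed samples
      shared <- obs[cand, , drop = FALSE] &
        matrix(obs[i, ], length(cand), ncol(values), byrow = TRUE)
      diff2 <- (values[cand, , drop = FALSE] -
                  matrix(values[i, ], length(cand), ncol(values),
                         byrow = TRUE))^2
      diff2[!shared] <- 0
      n_shared <- rowSums(shared)
      d <- sqrt(rowSums(diff2))
      usable <- n_shared > 0L
      if (!any(usable)) {
        out[i, j] <- mean(values[i, obs[i, ]])
        next
      }
      cand <- cand[usable]; d <- d[usable]
      ord <- order(d)
      take <- ord[seq_len(min(k, length(ord)))]
      dk <- d[take]
      vk <- values[cand[take], j]
      if (any(dk == 0)) {
        out[i, j] <- mean(vk[dk == 0])
      } else {
        w <- 1 / dk
        out[i, j] <- sum(w * vk) / sum(w)
      }
    }
  }
  out
}

#' Background-correct channel intensities
#'
#' Per sample and per channel, subtracts the channel's 5th-percentile
#' intensity (a deterministic surrogate for negative-control background)
#' and floors the result at 1.  The probe order within a channel is
#' preserved (the map is monotone).
#'
#' @param ds an [intensity_dataset()].
#' @param prob background quantile (default 0.05).
#' @return The background-corrected `intensity_dataset`.
#' @export
correct_background <- function(ds, prob = 0.05) {
  stopifnot(inherits(ds, "intensity_dataset"))
  bg_correct <- function(m) {
    bg <- apply(m, 2L, stats::quantile, probs = prob, names = FALSE)
    pmax(sweep(m, 2L, bg, "-"), 1)
  }
  ds$cy5 <- bg_correct(ds$cy5)
  ds$cy3 <- bg_correct(ds$cy3)
  ds
}

#' Correct dye colour bias by per-sample quantile mapping
#'
#' Per sample, monotonically rescales the Cy5 channel so its empirical
#' quantiles match the Cy3 channel's quantiles (the value at rank r of Cy5
#' becomes the value at rank r of Cy3); Cy3 is unchanged.  This removes the
#' systematic brightness difference between the two dyes without vendor
#' control probes.  A sample whose Cy5 channel is constant is left
#' untouched and flagged.
#'
#' @param ds a background-corrected [intensity_dataset()].
#' @return The corrected `intensity_dataset`; samples skipped because of a
#'   constant channel are listed in `attr(, "color_bias_skipped")`.
#' @export
correct_color_bias <- function(ds) {
  stopifnot(inherits(ds, "intensity_dataset"))
  skipped <- character()
  for (j in seq_len(ncol(ds$cy5))) {
    cy5 <- ds$cy5[, j]
    if (length(unique(cy5)) == 1L) {
      skipped <- c(skipped, colnames(ds$cy5)[j])
      next
    }
    corrected <- numeric(length(cy5))
    corrected[order(cy5)] <- sort(ds$cy3[, j])
    ds$cy5[, j] <- corrected
  }
  if (length(skipped)) {
    warning("constant Cy5 channel, colour-bias correction skipped for: ",
            paste(skipped, collapse = ", "), call. = FALSE)
    attr(ds, "color_bias_skipped") <- skipped
  }
  ds
}
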