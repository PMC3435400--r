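#' Compute M-values from channel intensities
#'
#' `M = log2((Cy5 + 1) / (Cy3 + 1))`, entry-wise; the +1 offsets keep the
#' ratio finite at zero intensity.  Cy5 is the methylated and Cy3 the
#' unmethylated channel, so positive M means more methylated.
#'
#' @param ds an [intensity_dataset()].
#' @return A `methylation_matrix` on the M scale (no entries marked
#'   imputed); the detection-failure mask `detection_p > 0.05` is attached
#'   as `attr(, "detection_failed")` for downstream imputation.
#' @export
compute_m_values <- function(ds) {
  stopifnot(inherits(ds, "intensity_dataset"))
  M <- log2((ds$cy5 + 1) / (ds$cy3 + 1))
  out <- methylation_matrix(M, scale = "M")
  attr(out, "detection_failed") <- ds$detection_p > 0.05
  out
}

#' Impute detection-failed entries of an M-value matrix
#'
#' Applies [knn_impute()] to the masked entries and records them in the
#' matrix's `imputed_mask`.
#'
#' @param m a `methylation_matrix` (M scale).
#' @param mask logical matrix marking detection-failed entries; defaults
#'   to the `detection_failed` attribute left by [compute_m_values()].
#' @param k number of neighbours.
#' @return The completed `methylation_matrix` with `imputed_mask` set.
#' @export
impute_methylation <- function(m, mask = NULL, k = 10) {
  stopifnot(inherits(m, "methylation_matrix"))
  if (is.null(mask)) mask <- attr(m, "detection_failed")
  if (is.null(mask)) stop("no imputation mask available", call. = FALSE)
  m$values <- knn_impute(m$values, mask, k = k)
  m$imputed_mask <- m$imputed_mask | mask
  m
}

#' Standardize a methylation matrix by per-sample z-scoring
#'
#' Each sample column is centred at its mean and divided by its standard
#' deviation (n - 1 denominator), putting all samples on a common scale so
#' that between-group differences can be read as z-score differences.
#'
#' @param m a `methylation_matrix` on the M scale.
#' @return A `methylation_matrix` on the Z scale (column mean 0, sd 1
#'   within 1e-8).  A constant column is an error naming the sample.
#' @export
zscore_standardize <- function(m) {
  stopifnot(inherits(m, "methylation_matrix"))
  V <- m$values
  mu <- colMeans(V)
  sd <- apply(V, 2L, stats::sd)
  if (any(sd == 0))
    stop("constant M-values in sample(s): ",
         paste(colnames(V)[sd == 0], collapse = ", "), call. = FALSE)
  Z <- sweep(sweep(V, 2L, mu, "-"), 2L, sd, "/")
  methylation_matrix(Z, scale = "Z", imputed_mask = m$imputed_mask)
}

#' Per-probe two-group t-tests
#'
#' Unpaired mode computes the Welch t statistic with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value for every probe (matrix
#' row).  Paired mode matches samples across the two groups by `subject`
#' and performs a one-sample t-test on the within-subject differences
#' (group1 minus group2).  A probe with zero variance in both groups (or
#' all-zero paired differences) is reported as `t = 0`, `p = 1` and
#' flagged `degenerate`, never as an error.
#'
#' @param Z a `methylation_matrix` or plain probe x sample matrix.
#' @param group per-sample labels with exactly two levels; the first level
#'   (factor order, or order of first appearance) is group 1, whose mean
#'   enters differences with a positive sign.
#' @param paired if `TRUE`, pair samples across groups by `subject`.
#' @param subject per-sample subject IDs, required when `paired = TRUE`;
#'   only complete pairs are used (>= 2 required).
#' @return data.frame with one row per probe: `t`, `df`, `p`, and
#'   `degenerate` (logical).
#' @export
two_group_test <- function(Z, group, paired = FALSE, subject = NULL) {
  V <- if (inherits(Z, "methylation_matrix")) Z$values else Z
  levs <- if (is.factor(group)) levels(group) else unique(as.character(group))
  group <- as.character(group)
  if (length(group) != ncol(V))
    stop("'group' must have one label per sample", call. = FALSE)
  levs <- levs[levs %in% group]
  if (length(levs) != 2L) stop("need exactly two groups", call. = FALSE)

  if (!paired) {
    X1 <- V[, group == levs[1L], drop = FALSE]
    X2 <- V[, group == levs[2L], drop = FALSE]
    n1 <- ncol(X1); n2 <- ncol(X2)
    if (n1 < 2L || n2 < 2L)
      stop("need >= 2 samples per group", call. = FALSE)
    m1 <- rowMeans(X1); m2 <- rowMeans(X2)
    v1 <- rowSums((X1 - m1)^2) / (n1 - 1)
    v2 <- rowSums((X2 - m2)^2) / (n2 - 1)
    se2 <- v1 / n1 + v2 / n2
    degen <- se2 == 0
    t <- ifelse(degen, 0, (m1 - m2) / sqrt(se2))
    df <- ifelse(degen, NA_real_,
                 se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)))
    p <- ifelse(degen, 1, 2 * stats::pt(-abs(t), df))
  } else {
    if (is.null(subject))
      stop("'subject' is required for a paired test", call. = FALSE)
    s1 <- subject[group == levs[1L]]
    s2 <- subject[group == levs[2L]]
    common <- intersect(s1, s2)
    if (length(common) < 2L)
      stop("need >= 2 complete subject pairs", call. = FALSE)
    i1 <- which(group == levs[1L])[match(common, s1)]
    i2 <- which(group == levs[2L])[match(common, s2)]
    D <- V[, i1, drop = FALSE] - V[, i2, drop = FALSE]
    n <- ncol(D)
    md <- rowMeans(D)
    vd <- rowSums((D - md)^2) / (n - 1)
    degen <- vd == 0 & md == 0
    t <- ifelse(vd == 0, ifelse(md == 0, 0, sign(md) * Inf),
                md / sqrt(vd / n))
    df <- rep(n - 1, nrow(D))
    p <- ifelse(vd == 0, ifelse(md == 0, 1, 0), 2 * stats::pt(-abs(t), df))
  }
  data.frame(t = t, df = df, p = p, degenerate = degen,
             row.names = rownames(V), stringsAsFactors = FALSE)
}

#' Storey q-values with smoother pi0 estimation
#'
#' Estimates the proportion of true null hypotheses pi0 on the grid
#' `lambda = 0, 0.05, ..., 0.90` via `pi0(lambda) = #\{p > lambda\} /
#' (m (1 - lambda))`, smooths the estimates with a cubic smoothing spline
#' (df = 3) and evaluates it at the largest lambda, clipping into (0, 1].
#' If the smoother output leaves (0, 1] (or cannot be computed), pi0
#' falls back to 1, in which case the q-values equal Benjamini-Hochberg
#' adjusted p-values.  Q-values are the step-up monotonization
#' `q(p_(i)) = min_{j >= i} pi0 * m * p_(j) / j`, capped at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param lambda estimation grid in \[0, 1).
#' @param pi0_method `"smoother"` (default) or `"fixed"` (use `pi0`
#'   as given).
#' @param pi0 fixed pi0 when `pi0_method = "fixed"` (default 1 = BH).
#' @return list with `q` (same order as `p`) and `fit` (class
#'   `qvalue_fit`: `pi0`, `lambda_grid`, `method`).
#' @export
storey_qvalues <- function(p, lambda = seq(0, 0.90, by = 0.05),
                           pi0_method = c("smoother", "fixed"), pi0 = 1) {
  pi0_method <- match.arg(pi0_method)
  m <- length(p)
  if (m < 1L) stop("need at least one p-value", call. = FALSE)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)

  if (pi0_method == "smoother") {
    lambda <- sort(unique(lambda))
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    est <- tryCatch({
      fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
      stats::predict(fit, x = max(lambda))$y
    }, error = function(e) NA_real_)
    if (is.na(est) || est <= 0 || est > 1) {
      pi0_hat <- 1
      method <- "fixed"          # smoother left (0,1]: fall back to BH
    } else {
      pi0_hat <- est
      method <- "smoother"
    }
  } else {
    if (is.na(pi0) || pi0 <= 0 || pi0 > 1)
      stop("fixed pi0 must lie in (0, 1]", call. = FALSE)
    pi0_hat <- pi0
    method <- "fixed"
  }

  ord <- order(p)
  q_ord <- pi0_hat * m * p[ord] / seq_len(m)
  q_ord <- rev(cummin(rev(q_ord)))
  q <- numeric(m)
  q[ord] <- pmin(q_ord, 1)
  fit <- structure(list(pi0 = pi0_hat, lambda_grid = lambda,
                        method = method), class = "qvalue_fit")
  list(q = q, fit = fit)
}

#' @export
print.qvalue_fit <- function(x, ...) {
  cat(sprintf("Storey q-value fit: pi0 = %.4f (%s)\n", x$pi0, x$method))
  invisible(x)
}

#' Call differentially methylated probes under the dual threshold
#'
#' Composes the group z-score difference, the per-probe two-group t-test
#' and Storey q-values, then calls a probe differentially methylated iff
#' `q <= q_threshold` AND `|z_diff| >= d_threshold`.  The z-score
#' difference is group1 minus group2 of per-probe group means on the
#' z-score scale; for reporting (volcano x-axis) it is also given as
#' `z_diff_log2 = sign(z_diff) * log2(|z_diff|)` (0 and flagged when
#' `z_diff` is exactly 0), so the default raw threshold of 2 corresponds
#' to 1 on the log2 axis.
#'
#' @param Z a Z-scale `methylation_matrix` (or plain matrix of per-sample
#'   z-scores).
#' @param group per-sample labels with two levels; the first-named level
#'   is group 1 (its higher methylation gives positive `z_diff`).
#' @param q_threshold q-value cut-off (default 0.05).
#' @param d_threshold absolute z-score-difference cut-off on the raw scale
#'   (default 2).
#' @param paired,subject see [two_group_test()].
#' @param manifest optional `probe_manifest` used to attach `target_id`
#'   and `gene` columns.
#' @param comparison optional name recorded on the result.
#' @param pi0_method,pi0 passed to [storey_qvalues()].
#' @return data.frame of class `differential_result`, one row per probe:
#'   `probe_id`, (`target_id`, `gene`,) `mean_z_group1`, `mean_z_group2`,
#'   `z_diff`, `z_diff_log2`, `zdiff_degenerate`, `t_stat`, `p_value`,
#'   `q_value`, `called`.  The `qvalue_fit`, thresholds, group levels and
#'   comparison name are attached as attributes; see
#'   [summary.differential_result()].
#' @export
call_differential <- function(Z, group, q_threshold = 0.05, d_threshold = 2,
                              paired = FALSE, subject = NULL,
                              manifest = NULL, comparison = NULL,
                              pi0_method = "smoother", pi0 = 1) {
  V <- if (inherits(Z, "methylation_matrix")) Z$values else Z
  if (q_threshold <= 0 || q_threshold > 1)
    stop("q_threshold must lie in (0, 1]", call. = FALSE)
  if (d_threshold < 0) stop("d_threshold must be >= 0", call. = FALSE)
  levs <- if (is.factor(group)) levels(group) else unique(as.character(group))
  group <- as.character(group)
  levs <- levs[levs %in% group]
  if (length(levs) != 2L) stop("need exactly two groups", call. = FALSE)

  tt <- two_group_test(V, factor(group, levels = levs), paired = paired,
                       subject = subject)
  m1 <- rowMeans(V[, group == levs[1L], drop = FALSE])
  m2 <- rowMeans(V[, group == levs[2L], drop = FALSE])
  z_diff <- m1 - m2
  zero <- z_diff == 0
  z_diff_log2 <- ifelse(zero, 0, sign(z_diff) * log2(abs(z_diff)))
  qv <- storey_qvalues(tt$p, pi0_method = pi0_method, pi0 = pi0)

  res <- data.frame(probe_id = rownames(V),
                    mean_z_group1 = m1, mean_z_group2 = m2,
                    z_diff = z_diff, z_diff_log2 = z_diff_log2,
                    zdiff_degenerate = zero,
                    t_stat = tt$t, p_value = tt$p, q_value = qv$q,
                    called = qv$q <= q_threshold &
                      abs(z_diff) >= d_threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(manifest)) {
    i <- match(res$probe_id, manifest$probe_id)
    res$target_id <- manifest$target_id[i]
    res$gene <- manifest$gene[i]
    res <- res[, c("probe_id", "target_id", "gene",
                   setdiff(names(res), c("probe_id", "target_id", "gene")))]
  }
  attr(res, "qvalue_fit") <- qv$fit
  attr(res, "q_threshold") <- q_threshold
  attr(res, "d_threshold") <- d_threshold
  attr(res, "groups") <- levs
  attr(res, "comparison") <- comparison
  class(res) <- c("differential_result", "data.frame")
  res
}

#' @export
print.differential_result <- function(x, ...) {
  cmp <- attr(x, "comparison")
  g <- attr(x, "groups")
  cat(sprintf("Differential methylation result%s: %s vs %s\n",
              if (is.null(cmp)) "" else paste0(" '", cmp, "'"),
              g[1L], g[2L]))
  cat(sprintf("  %d probes tested, %d called (q <= %g and |z_diff| >= %g); pi0 = %.3f\n",
              nrow(x), sum(x$called), attr(x, "q_threshold"),
              attr(x, "d_threshold"), attr(x, "qvalue_fit")$pi0))
  invisible(x)
}

#' Summarize a differential-methylation result
#'
#' @param object a `differential_result`.
#' @param ... unused.
#' @return list with the comparison name, group levels, thresholds,
#'   number tested/called, the pi0 estimate, and the called subset sorted
#'   by q-value.
#' @export
summary.differential_result <- function(object, ...) {
  called <- object[object$called, , drop = FALSE]
  called <- called[order(called$q_value, -abs(called$z_diff)), ,
                   drop = FALSE]
  out <- list(comparison = attr(object, "comparison"),
              groups = attr(object, "groups"),
              q_threshold = attr(object, "q_threshold"),
              d_threshold = attr(object, "d_threshold"),
              n_tested = nrow(object), n_called = sum(object$called),
              pi0 = attr(object, "qvalue_fit")$pi0,
              called = as.data.frame(called))
  class(out) <- "summary.differential_result"
  out
}

#' @export
print.summary.differential_result <- function(x, ...) {
  cat(sprintf("Comparison %s: %s vs %s — %d/%d probes called (pi0 = %.3f)\n",
              if (is.null(x$comparison)) "(unnamed)" else x$comparison,
              x$groups[1L], x$groups[2L], x$n_called, x$n_tested, x$pi0))
  if (x$n_called > 0)
    print(utils::head(x$called[, intersect(
      c("probe_id", "target_id", "z_diff", "z_diff_log2", "q_value"),
      names(x$called))], 10L))
  invisible(x)
}

#' Volcano-plot coordinates for a differential result
#'
#' @param res a `differential_result`.
#' @return data.frame with `probe_id`, `z_diff_log2` (x), `neg_log10_q`
#'   (y) and `called`.
#' @export
volcano_data <- function(res) {
  stopifnot(inherits(res, "differential_result"))
  data.frame(probe_id = res$probe_id, z_diff_log2 = res$z_diff_log2,
             neg_log10_q = -log10(pmax(res$q_value, 1e-300)),
             called = res$called, stringsAsFactors = FALSE)
}

#' Kruskal-Wallis test with Dunn's pairwise comparisons
#'
#' The omnibus Kruskal-Wallis H (tie-corrected, chi-square p-value) via
#' [stats::kruskal.test()], followed by Dunn's z statistic for every pair
#' of groups,
#' `z = (Rbar_A - Rbar_B) / sqrt((N(N+1)/12 - T) (1/n_A + 1/n_B))`
#' with tie correction `T = sum(t^3 - t) / (12 (N - 1))`, and a
#' multiple-comparison adjustment over all pairs (Bonferroni by default,
#' matching Dunn's classical procedure).
#'
#' @param values numeric observations.
#' @param groups group label per observation (>= 3 groups, each with >= 2
#'   observations).
#' @param p_adjust adjustment method for the pairwise p-values (any
#'   [stats::p.adjust()] method).
#' @return list with `H`, `df`, `p`, and `pairwise` (data.frame
#'   `group1`, `group2`, `z`, `p_unadjusted`, `p_adjusted`).
#' @export
kruskal_dunn <- function(values, groups, p_adjust = "bonferroni") {
  groups <- as.character(groups)
  if (length(values) != length(groups))
    stop("'values' and 'groups' must have equal length", call. = FALSE)
  levs <- unique(groups)
  if (length(levs) < 3L) stop("need >= 3 groups", call. = FALSE)
  nper <- table(groups)
  if (any(nper < 2L)) stop("each group needs >= 2 observations",
                           call. = FALSE)
  if (length(unique(values)) == 1L) {
    # degenerate all-tied data: no evidence against the null
    pairs <- utils::combn(levs, 2L)
    return(list(H = 0, df = length(levs) - 1L, p = 1,
                pairwise = data.frame(group1 = pairs[1L, ],
                                      group2 = pairs[2L, ], z = 0,
                                      p_unadjusted = 1, p_adjusted = 1,
                                      stringsAsFactors = FALSE)))
  }
  kw <- stats::kruskal.test(values, factor(groups, levels = levs))

  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  pairs <- utils::combn(levs, 2L)
  pw <- apply(pairs, 2L, function(ab) {
    nA <- sum(groups == ab[1L]); nB <- sum(groups == ab[2L])
    denom <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / nA + 1 / nB))
    z <- if (denom > 0) (rbar[[ab[1L]]] - rbar[[ab[2L]]]) / denom else 0
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  pairwise <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                         z = pw["z", ], p_unadjusted = pw["p", ],
                         p_adjusted = stats::p.adjust(pw["p", ],
                                                      method = p_adjust),
                         row.names = NULL, stringsAsFactors = FALSE)
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p = kw$p.value, pairwise = pairwise)
}
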