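# Distance-weighted discrimination (DWD).
#
# DWD finds a separating direction by minimizing the sum of inverse
# margins plus a penalty on slack:
#
#     minimize  sum_i 1/r_i + C * sum_i xi_i
#     s.t.      r_i = y_i (w . x_i + b) + xi_i > 0,  xi_i >= 0,  ||w||_2 <= 1
#
# Profiling out the slacks gives the equivalent smooth convex loss
#     V(m) = 1/m            for m >= 1/sqrt(C)
#          = 2*sqrt(C) - C*m  otherwise
# applied to the margins m_i = y_i (w . x_i + b), minimized over the unit
# ball ||w|| <= 1.  V is convex and continuously differentiable, so a
# projected-gradient scheme with backtracking converges to the global
# optimum; that is the solver used here (recorded as backend "gradient").
# Unlike the SVM hinge loss, every point keeps a nonzero pull on the
# direction, which is what makes DWD robust in high-dimension/low-sample
# settings and suitable for batch adjustment.

dwd_loss <- function(margin, C) {
  thresh <- 1 / sqrt(C)
  ifelse(margin >= thresh, 1 / margin, 2 * sqrt(C) - C * margin)
}

dwd_loss_grad <- function(margin, C) {
  thresh <- 1 / sqrt(C)
  ifelse(margin >= thresh, -1 / margin^2, -C)
}

#' Default DWD penalty
#'
#' The scale-invariant heuristic `100 / median^2` of the pairwise
#' Euclidean distances between points of opposite class.
#'
#' @param X sample x feature matrix.
#' @param y labels in \{-1, +1\}.
#' @return positive scalar penalty.
#' @export
dwd_default_penalty <- function(X, y) {
  a <- X[y > 0, , drop = FALSE]
  b <- X[y < 0, , drop = FALSE]
  # cross-class pairwise distances
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  med <- stats::median(sqrt(pmax(d2, 0)))
  if (med <= 0) stop("zero median between-class distance", call. = FALSE)
  100 / med^2
}

#' Fit a distance-weighted-discrimination direction
#'
#' @param X sample x feature numeric matrix (n >= 2).
#' @param y numeric or factor labels; coerced to -1/+1 (both classes must
#'   be present).
#' @param penalty_C slack penalty `C`; `NULL` (default) uses
#'   [dwd_default_penalty()].
#' @param max_iter,tol projected-gradient iteration cap and relative
#'   objective-change tolerance.
#' @return Object of class `dwd`: list with unit-norm direction `w` (one
#'   weight per feature), intercept `b`, `penalty_C`, `converged`,
#'   `objective`, `iterations`, and `backend` (`"gradient"`).
#' @examples
#' X <- rbind(matrix(rnorm(40, -2), 20), matrix(rnorm(40, 2), 20))
#' fit <- fit_dwd(X, rep(c(-1, 1), each = 20))
#' fit$w
#' @export
fit_dwd <- function(X, y, penalty_C = NULL, max_iter = 5000, tol = 1e-10) {
  X <- as.matrix(X)
  if (is.factor(y) || is.character(y)) {
    lev <- sort(unique(as.character(y)))
    if (length(lev) != 2L) stop("need exactly two classes", call. = FALSE)
    y <- ifelse(as.character(y) == lev[2L], 1, -1)
  }
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop("labels must be coercible to -1/+1",
                                  call. = FALSE)
  if (length(unique(y)) < 2L) stop("single-class input", call. = FALSE)
  n <- nrow(X)
  if (n < 2L || length(y) != n) stop("need n >= 2 samples with labels",
                                     call. = FALSE)
  if (all(apply(X, 2L, stats::sd) == 0)) stop("zero-variance data",
                                              call. = FALSE)
  C <- if (is.null(penalty_C)) dwd_default_penalty(X, y) else penalty_C
  if (C <= 0) stop("penalty_C must be positive", call. = FALSE)

  # init: normalized mean-difference direction, intercept at the midpoint
  mu1 <- colMeans(X[y > 0, , drop = FALSE])
  mu0 <- colMeans(X[y < 0, , drop = FALSE])
  w <- mu1 - mu0
  nw <- sqrt(sum(w^2))
  w <- if (nw > 0) w / nw else rep(1 / sqrt(ncol(X)), ncol(X))
  b <- -sum(w * (mu1 + mu0)) / 2

  obj_of <- function(w, b) sum(dwd_loss(y * (X %*% w + b), C))
  obj <- obj_of(w, b)
  step <- 1 / (C * max(1, sum(X^2) / n))   # conservative initial step
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    margins <- y * (X %*% w + b)
    g <- dwd_loss_grad(margins, C) * y
    gw <- drop(crossprod(X, g))
    gb <- sum(g)
    # backtracking line search on the projected step
    repeat {
      w_new <- w - step * gw
      nw <- sqrt(sum(w_new^2))
      if (nw > 1) w_new <- w_new / nw
      b_new <- b - step * gb
      obj_new <- obj_of(w_new, b_new)
      if (obj_new <= obj + 1e-12 || step < 1e-18) break
      step <- step / 2
    }
    delta <- obj - obj_new
    w <- w_new; b <- b_new; obj <- obj_new
    step <- step * 1.25
    if (delta >= 0 && delta <= tol * (abs(obj) + 1e-12)) {
      converged <- TRUE
      break
    }
  }
  w_out <- drop(w)
  nw <- sqrt(sum(w_out^2))
  if (nw > 0) { b <- b / nw; w_out <- w_out / nw }  # report unit direction
  names(w_out) <- colnames(X)
  structure(list(w = w_out, b = b, penalty_C = C, converged = converged,
                 objective = obj, iterations = it, backend = "gradient"),
            class = "dwd")
}

#' @export
print.dwd <- function(x, ...) {
  cat(sprintf("DWD fit (%s backend): %d features, C = %.4g, %s after %d iterations\n",
              x$backend, length(x$w), x$penalty_C,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' @export
coef.dwd <- function(object, ...) c(intercept = object$b, object$w)

#' @export
predict.dwd <- function(object, newdata, type = c("score", "class"), ...) {
  type <- match.arg(type)
  s <- drop(as.matrix(newdata) %*% object$w + object$b)
  if (type == "score") s else ifelse(s >= 0, 1, -1)
}

#' Remove batch effects by translation along DWD directions
#'
#' For each pair-wise batch step (batches beyond the second are merged
#' sequentially in order of first appearance), a DWD direction is fitted
#' between the two groups, all samples are projected on it, and each
#' group is translated along the direction so both group means land on the
#' pooled mean projection.  Each batch therefore undergoes a rigid
#' translation: within-batch geometry is preserved exactly, and after
#' adjustment the batch-mean difference along each fitted direction is 0
#' (to within 1e-8).
#'
#' @param M a `methylation_matrix` (M scale) or plain probe x sample
#'   matrix.
#' @param batches batch label per sample (length = number of samples).
#' @param penalty_C optional DWD penalty, `NULL` for the default heuristic.
#' @param guard optional per-sample labels of the comparison of interest;
#'   if the batch labels are perfectly confounded (1:1) with the guard
#'   labels a warning is issued, because adjustment would remove the
#'   signal.
#' @return The adjusted object (same class as the input); fitted `dwd`
#'   models are attached as `attr(, "dwd_models")`.
#' @export
dwd_batch_adjust <- function(M, batches, penalty_C = NULL, guard = NULL) {
  mm <- inherits(M, "methylation_matrix")
  V <- if (mm) M$values else M
  batches <- as.character(batches)
  if (length(batches) != ncol(V))
    stop("'batches' must have one label per sample", call. = FALSE)
  levs <- unique(batches)
  if (length(levs) < 2L) return(M)              # one batch: nothing to adjust
  if (any(table(batches) < 2L))
    stop("each batch needs >= 2 samples", call. = FALSE)
  if (!is.null(guard)) {
    if (length(unique(paste(batches, guard))) == length(levs) &&
        length(unique(guard)) == length(levs))
      warning("batch labels are perfectly confounded with the comparison ",
              "of interest; adjustment may remove signal", call. = FALSE)
  }

  X <- t(V)                                     # samples x probes
  fits <- list()
  merged <- batches == levs[1L]
  for (b in levs[-1L]) {
    cur <- batches == b
    y <- ifelse(cur, 1, -1)[merged | cur]
    idx <- which(merged | cur)
    fit <- fit_dwd(X[idx, , drop = FALSE], y, penalty_C = penalty_C)
    proj <- drop(X[idx, , drop = FALSE] %*% fit$w)
    pooled <- mean(proj)
    for (grp in list(which(merged), which(cur))) {
      shift <- mean(drop(X[grp, , drop = FALSE] %*% fit$w)) - pooled
      X[grp, ] <- X[grp, ] - outer(rep(shift, length(grp)), fit$w)
    }
    fits[[b]] <- fit
    merged <- merged | cur
  }
  V <- t(X)
  dimnames(V) <- dimnames(if (mm) M$values else M)
  out <- if (mm) { M$values <- V; M } else V
  attr(out, "dwd_models") <- fits
  out
}
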