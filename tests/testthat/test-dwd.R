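# Direct numerical minimization of the DWD objective (profiled slack
# form) over the unit ball, used as an independent oracle.
dwd_objective <- function(X, y, C) {
  function(par) {
    p <- ncol(X)
    v <- par[seq_len(p)]; b <- par[p + 1L]
    nv <- sqrt(sum(v^2))
    w <- if (nv > 1) v / nv else v
    m <- y * (X %*% w + b)
    th <- 1 / sqrt(C)
    sum(ifelse(m >= th, 1 / m, 2 * sqrt(C) - C * m))
  }
}

test_that("the symmetric 1-D problem has the closed symmetric solution", {
  X <- matrix(c(-1, 1), ncol = 1)
  fit <- fit_dwd(X, c(-1, 1), penalty_C = 25)
  expect_equal(unname(fit$w), 1, tolerance = 1e-6)
  expect_equal(fit$b, 0, tolerance = 1e-5)
  # 1-D brute force over b-hat confirms b = 0: minimize 1/(1-b)+1/(1+b)
  bgrid <- seq(-0.9, 0.9, by = 1e-4)
  expect_equal(bgrid[which.min(1 / (1 - bgrid) + 1 / (1 + bgrid))], 0,
               tolerance = 1e-3)
})

test_that("reflection symmetry of data and labels forces a zero intercept", {
  set.seed(31)
  A <- matrix(rnorm(40), 20, 2) + 2
  X <- rbind(A, -A)
  y <- rep(c(1, -1), each = 20)
  fit <- fit_dwd(X, y)
  expect_equal(fit$b, 0, tolerance = 1e-4)
  expect_equal(sqrt(sum(fit$w^2)), 1, tolerance = 1e-6)
})

test_that("well-separated clouds give the separating axis", {
  set.seed(32)
  n <- 50
  X <- rbind(cbind(rnorm(n), rnorm(n)), cbind(rnorm(n) + 10, rnorm(n)))
  y <- rep(c(-1, 1), each = n)
  fit <- fit_dwd(X, y)
  expect_gte(abs(fit$w[1L]), 0.99)
  expect_true(all(y * (X %*% fit$w + fit$b) > 0))    # separable: all margins +
})

test_that("the solver matches direct numerical minimization on random instances", {
  set.seed(33)
  cosines <- replicate(20, {
    n <- sample(10:40, 1); p <- sample(2:20, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rep_len(c(-1, 1), n)
    X[y > 0, ] <- X[y > 0, ] + 2.5               # separable-ish shift
    fit <- fit_dwd(X, y)
    f <- dwd_objective(X, y, fit$penalty_C)
    o <- stats::optim(c(fit$w * 0.9 + rnorm(p, 0, 0.05), fit$b), f,
                      method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-14))
    w2 <- o$par[seq_len(p)]
    w2 <- w2 / sqrt(sum(w2^2))
    abs(sum(fit$w * w2))
  })
  expect_true(all(cosines >= 0.99))
})

test_that("degenerate DWD inputs are rejected", {
  X <- matrix(rnorm(10), 5, 2)
  expect_error(fit_dwd(X, rep(1, 5)), "single-class")
  expect_error(fit_dwd(matrix(1, 4, 2), c(-1, -1, 1, 1)), "zero-variance")
})

test_that("batch adjustment is a rigid per-batch translation", {
  set.seed(34)
  V <- matrix(rnorm(40 * 12), 40, 12,
              dimnames = list(sprintf("p%02d", 1:40), sprintf("s%02d", 1:12)))
  batches <- rep(c("A", "B"), each = 6)
  V[, batches == "B"] <- V[, batches == "B"] + 0.8
  adj <- dwd_batch_adjust(V, batches)
  for (b in c("A", "B")) {
    idx <- which(batches == b)
    expect_equal(as.vector(stats::dist(t(V[, idx]))),
                 as.vector(stats::dist(t(adj[, idx]))), tolerance = 1e-9)
  }
  # batch-mean difference along the fitted direction is removed
  w <- attr(adj, "dwd_models")$B$w
  proj <- drop(t(adj) %*% w)
  expect_lt(abs(mean(proj[batches == "A"]) - mean(proj[batches == "B"])),
            1e-8)
})

test_that("a single batch returns the input unchanged", {
  V <- matrix(rnorm(20), 4, 5,
              dimnames = list(paste0("p", 1:4), paste0("s", 1:5)))
  expect_identical(dwd_batch_adjust(V, rep("A", 5)), V)
})

test_that("shuffled labels over i.i.d. data move samples only slightly", {
  set.seed(35)
  V <- matrix(rnorm(30 * 20), 30, 20,
              dimnames = list(sprintf("p%02d", 1:30), sprintf("s%02d", 1:20)))
  batches <- rep(c("A", "B"), 10)                  # no systematic shift
  adj <- dwd_batch_adjust(V, batches)
  shift <- sqrt(colSums((adj - V)^2))
  # the removed translation cannot exceed the null spread of mean
  # projections (order sd/sqrt(n)); generous bound of 3 such units
  expect_true(all(shift <= 3 * sqrt(1 / 10) * 3))
})

test_that("an injected batch displacement is recovered along its direction", {
  sim <- simulate_dataset(experiment_config(seed = 36, n_probes = 500))
  ds <- correct_color_bias(correct_background(sim$dataset))
  m <- compute_m_values(ds)
  set.seed(37)
  u <- rnorm(nrow(m$values)); u <- u / sqrt(sum(u^2))
  delta <- 5 * 0.5                                  # 5 x noise SD
  batches <- rep_len(c("A", "B"), ncol(m$values))
  m$values[, batches == "B"] <- m$values[, batches == "B"] + delta * u
  adj <- dwd_batch_adjust(m, batches)
  resid <- abs(sum(u * (rowMeans(adj$values[, batches == "B"]) -
                          rowMeans(adj$values[, batches == "A"]))))
  expect_lte(resid, 0.1 * delta)
})

test_that("re-adjustment only chases refit noise", {
  set.seed(38)
  V <- matrix(rnorm(300 * 40), 300, 40,
              dimnames = list(sprintf("p%03d", 1:300),
                              sprintf("s%02d", 1:40)))
  batches <- rep(c("A", "B"), each = 20)
  V[, batches == "B"] <- V[, batches == "B"] + 1.5
  once <- dwd_batch_adjust(V, batches)
  twice <- dwd_batch_adjust(once, batches)
  # once the systematic displacement is gone, a refit can only chase
  # sampling noise: the second-pass translation is a small fraction of
  # the first-pass one
  expect_lt(max(abs(twice - once)), 0.1 * max(abs(once - V)))
})

test_that("batch confounded with the comparison of interest warns", {
  set.seed(39)
  V <- matrix(rnorm(20 * 8), 20, 8,
              dimnames = list(sprintf("p%02d", 1:20), sprintf("s%02d", 1:8)))
  batches <- rep(c("A", "B"), each = 4)
  guard <- rep(c("AEC", "PBMC"), each = 4)          # 1:1 with batch
  expect_warning(dwd_batch_adjust(V, batches, guard = guard),
                 "confounded")
})
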