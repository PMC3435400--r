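make_mm <- function(V) {
  dimnames(V) <- list(sprintf("p%03d", seq_len(nrow(V))),
                      sprintf("s%03d", seq_len(ncol(V))))
  methylation_matrix(V, scale = "M")
}

test_that("M-values follow the offset log-ratio definition", {
  ds <- toy_dataset(4, 1)
  ds$cy3 <- ds$cy5
  expect_true(all(compute_m_values(ds)$values == 0))

  ds$cy5[] <- 1023; ds$cy3[] <- 255
  expect_true(all(compute_m_values(ds)$values == 2))  # log2(1024/256)

  ds$cy5[] <- 0; ds$cy3[] <- 0
  expect_true(all(compute_m_values(ds)$values == 0))  # offsets keep it finite
})

test_that("z-scoring centres and scales each sample column", {
  m <- make_mm(matrix(c(1, 2, 3, 4, 8, 6, 0, -1, 5, 2, 2.5, 7), 3, 4))
  z <- zscore_standardize(m)
  expect_equal(z$values[, 1L], c(p001 = -1, p002 = 0, p003 = 1))
  expect_equal(unname(colMeans(z$values)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(z$values, 2, sd)), rep(1, 4), tolerance = 1e-12)

  # independent two-pass mean/sd computation
  V <- matrix(c(0.4, -1.2, 3.3, 2.0, 5.5, -0.7, 1.1, 0.0, 2.2, -3.3, 4.4,
                0.5), 4, 3)
  z2 <- zscore_standardize(make_mm(V))
  for (j in 1:3) {
    mu <- sum(V[, j]) / 4
    sd_j <- sqrt(sum((V[, j] - mu)^2) / 3)
    expect_equal(unname(z2$values[, j]), (V[, j] - mu) / sd_j,
                 tolerance = 1e-12)
  }

  m$values[, 2L] <- 5
  expect_error(zscore_standardize(m), "s002")
})

test_that("row-wise Welch statistics match stats::t.test", {
  # textbook-style case
  g1 <- c(2.1, 2.0, 1.9); g2 <- c(1.0, 1.1, 0.9)
  V <- matrix(c(g1, g2), 1, 6,
              dimnames = list("p1", paste0("s", 1:6)))
  got <- two_group_test(V, rep(c("a", "b"), each = 3))
  ref <- stats::t.test(g1, g2)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)

  # randomized matrix vs the per-row oracle, unequal group sizes
  set.seed(51)
  V <- matrix(rnorm(50 * 11), 50, 11,
              dimnames = list(sprintf("p%02d", 1:50), sprintf("s%02d", 1:11)))
  grp <- rep(c("a", "b"), c(5, 6))
  got <- two_group_test(V, grp)
  for (i in seq_len(nrow(V))) {
    ref <- stats::t.test(V[i, grp == "a"], V[i, grp == "b"])
    expect_equal(got$t[i], unname(ref$statistic), tolerance = 1e-8)
    expect_equal(got$p[i], ref$p.value, tolerance = 1e-8)
  }
})

test_that("identical groups give t = 0, p = 1; zero variance is flagged", {
  V <- matrix(rep(c(1, 2, 3), 2), 1, 6,
              dimnames = list("p1", paste0("s", 1:6)))
  got <- two_group_test(V, rep(c("a", "b"), each = 3))
  expect_equal(got$t, 0)

  V[] <- 7                                 # constant everywhere
  got <- two_group_test(V, rep(c("a", "b"), each = 3))
  expect_equal(got$t, 0)
  expect_equal(got$p, 1)
  expect_true(got$degenerate)
})

test_that("paired mode is a one-sample t on within-subject differences", {
  set.seed(52)
  n <- 8
  V <- matrix(rnorm(20 * 2 * n), 20, 2 * n,
              dimnames = list(sprintf("p%02d", 1:20),
                              sprintf("s%02d", 1:(2 * n))))
  grp <- rep(c("AEC", "PBMC"), each = n)
  subj <- rep(sprintf("u%02d", 1:n), times = 2)
  got <- two_group_test(V, grp, paired = TRUE, subject = subj)
  for (i in c(1, 7, 20)) {
    ref <- stats::t.test(V[i, 1:n], V[i, n + 1:n], paired = TRUE)
    expect_equal(got$t[i], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p[i], ref$p.value, tolerance = 1e-10)
  }
  # paired and unpaired t agree in sign probe-wise
  unp <- two_group_test(V, grp)
  nz <- got$t != 0 & unp$t != 0
  expect_true(all(sign(got$t[nz]) == sign(unp$t[nz])))
})

test_that("q-values with pi0 = 1 reproduce Benjamini-Hochberg exactly", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  q <- storey_qvalues(p, pi0_method = "fixed", pi0 = 1)
  expect_equal(q$q, rep(0.04, 4))          # hand BH: min_j>=i m p_(j)/j

  expect_equal(storey_qvalues(0.03, pi0_method = "fixed", pi0 = 1)$q, 0.03)

  set.seed(53)
  for (rep in 1:5) {
    p <- runif(200)^sample(c(1, 2), 1)
    q <- storey_qvalues(p, pi0_method = "fixed", pi0 = 1)
    expect_equal(q$q, stats::p.adjust(p, method = "BH"), tolerance = 1e-12)
  }
})

test_that("q-values are monotone in p and bounded by the pre-monotonized value", {
  set.seed(54)
  p <- runif(500)
  out <- storey_qvalues(p)
  ord <- order(p)
  expect_true(all(diff(out$q[ord]) >= -1e-15))
  raw <- out$fit$pi0 * length(p) * p[ord] / seq_along(p)
  expect_true(all(out$q[ord] <= pmin(raw, 1) + 1e-15))
  expect_true(out$fit$pi0 > 0 && out$fit$pi0 <= 1)
})

test_that("the pi0 smoother is calibrated under the uniform null", {
  hits <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    fit <- storey_qvalues(runif(1000))$fit
    fit$pi0 >= 0.8 && fit$pi0 <= 1
  }, logical(1))
  expect_gte(sum(hits), 19L)
})

test_that("dual-threshold calling obeys both cut-offs and the log2 convention", {
  set.seed(55)
  V <- matrix(rnorm(100 * 12), 100, 12,
              dimnames = list(sprintf("p%03d", 1:100),
                              sprintf("s%02d", 1:12)))
  # inject strong shifts in 10 probes
  V[1:10, 7:12] <- V[1:10, 7:12] + 4
  grp <- rep(c("a", "b"), each = 6)
  res <- call_differential(V, grp, q_threshold = 0.05, d_threshold = 2)
  expect_true(all(res$called ==
                    (res$q_value <= 0.05 & abs(res$z_diff) >= 2)))
  # threshold equivalence of the signed log2 axis:
  # |z_diff| >= 2  <=>  log2|z_diff| >= 1  <=>  sign(z) * z_diff_log2 >= 1
  nz <- !res$zdiff_degenerate
  expect_equal(abs(res$z_diff[nz]) >= 2,
               sign(res$z_diff[nz]) * res$z_diff_log2[nz] >= 1)
  # every called probe sits beyond the +/-1 lines on the log2 axis
  expect_true(all(abs(res$z_diff_log2[res$called]) >= 1))
  # z_diff direction is group1 - group2
  expect_true(all(res$z_diff[1:10] < 0))   # group "a" is less methylated

  # extreme thresholds: everything / nothing
  res_all <- call_differential(V, grp, q_threshold = 1, d_threshold = 0)
  expect_true(all(res_all$called))
  res_none <- call_differential(V, grp, q_threshold = 1e-12,
                                d_threshold = 0)
  expect_false(any(res_none$called))
})

test_that("a q-passing probe below the z-difference cut-off is not called", {
  set.seed(56)
  # tiny within-group noise: huge t (tiny q) but small mean shift
  V <- matrix(rnorm(2 * 12, sd = 0.01), 2, 12,
              dimnames = list(c("p1", "p2"), sprintf("s%02d", 1:12)))
  V[1L, 7:12] <- V[1L, 7:12] + 1.5          # |z_diff| = 1.5 < 2
  res <- call_differential(V, rep(c("a", "b"), each = 6))
  expect_lte(res$q_value[1L], 0.05)
  expect_lt(abs(res$z_diff[1L]), 2)
  expect_false(res$called[1L])
})

test_that("the signed log2 z-difference inverts the reported table convention", {
  # a reported log2 value of -1.14 corresponds to a raw difference of
  # -2^1.14 ~ -2.20
  raw <- -2^1.14
  expect_equal(sign(raw) * log2(abs(raw)), -1.14, tolerance = 1e-12)
  expect_equal(raw, -2.2039, tolerance = 1e-4)
})

test_that("Kruskal-Wallis H and Dunn z match hand rank computations", {
  # groups {1,2},{3,4},{5,6}: ranks are 1..6, rank sums 3, 7, 11
  # H = 12/(N(N+1)) * sum(R_g^2/n_g) - 3(N+1)
  v <- c(1, 2, 3, 4, 5, 6)
  g <- rep(c("a", "b", "c"), each = 2)
  out <- kruskal_dunn(v, g)
  H_hand <- 12 / (6 * 7) * (9 / 2 + 49 / 2 + 121 / 2) - 3 * 7
  expect_equal(out$H, H_hand, tolerance = 1e-12)
  expect_equal(out$df, 2L)
  # Dunn z for (a, c): (1.5 - 5.5) / sqrt((6*7/12) * (1/2 + 1/2))
  z_hand <- (1.5 - 5.5) / sqrt(3.5)
  i <- which(out$pairwise$group1 == "a" & out$pairwise$group2 == "c")
  expect_equal(out$pairwise$z[i], z_hand, tolerance = 1e-12)
  expect_equal(out$pairwise$p_adjusted,
               pmin(out$pairwise$p_unadjusted * 3, 1), tolerance = 1e-12)
})

test_that("constant data across groups gives H = 0, p = 1", {
  out <- kruskal_dunn(rep(5, 9), rep(c("a", "b", "c"), each = 3))
  expect_equal(out$H, 0)
  expect_equal(out$p, 1)
  expect_true(all(out$pairwise$p_adjusted == 1))
})

test_that("the H statistic is exchangeable under label permutation", {
  set.seed(57)
  v <- rnorm(18)
  g <- rep(c("a", "b", "c"), each = 6)
  h1 <- sort(replicate(20, kruskal_dunn(v, sample(g))$H))
  h2 <- sort(replicate(20, kruskal_dunn(sample(v), g)$H))
  # both permutation schemes draw from the same null distribution
  expect_lt(abs(median(h1) - median(h2)), 2.5)
  expect_error(kruskal_dunn(v[1:7], c("a", "a", "a", "b", "b", "b", "c")),
               ">= 2 observations")
})
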