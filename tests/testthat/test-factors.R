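test_that("parallel analysis recovers a known factor count and nulls", {
  # 3 orthogonal factors, loadings 0.8, noise sd 0.4, n = 42
  suggests <- vapply(1:20, function(i) {
    withr::with_seed(5000 + i, {
      n <- 42; per <- 7
      f <- matrix(rnorm(n * 3), n, 3)
      x <- f[, rep(1:3, each = per)] * 0.8 +
        matrix(rnorm(n * 3 * per, 0, 0.4), n, 3 * per)
      parallel_analysis(cor(x), n_sim = 100, seed = i, n_obs = n)$n_factors
    })
  }, integer(1))
  expect_gte(mean(suggests == 3L), 0.9)

  # pure noise: the stricter 0.95-quantile variant suggests none
  nulls <- vapply(1:20, function(i) {
    withr::with_seed(6000 + i,
      parallel_analysis(cor(matrix(rnorm(42 * 20), 42, 20)),
                        n_sim = 100, quantile = 0.95, seed = i,
                        n_obs = 42)$n_factors)
  }, integer(1))
  expect_gte(mean(nulls == 0L), 0.8)
  # mean-rule null suggestion stays small (0 or 1 typically)
  null_mean <- vapply(1:20, function(i) {
    withr::with_seed(7000 + i,
      parallel_analysis(cor(matrix(rnorm(42 * 20), 42, 20)),
                        n_sim = 100, seed = i, n_obs = 42)$n_factors)
  }, integer(1))
  expect_lte(stats::median(null_mean), 1)
})

test_that("parallel-analysis suggestion is non-increasing in the quantile", {
  withr::with_seed(21, {
    n <- 50
    f <- matrix(rnorm(n * 2), n, 2)
    x <- f[, rep(1:2, each = 6)] * 0.7 + matrix(rnorm(n * 12, 0, 0.6), n, 12)
    R <- cor(x)
  })
  ks <- vapply(c(0.05, 0.5, 0.95, 0.99), function(q)
    parallel_analysis(R, n_sim = 150, quantile = q, seed = 3,
                      n_obs = 50)$n_factors, integer(1))
  expect_true(all(diff(ks) <= 0))
  expect_warning(parallel_analysis(R, n_sim = 20, seed = 1, n_obs = 50),
                 "unstable")
})

test_that("minres solves the equal-loading one-factor model exactly", {
  p <- 8; lam <- 0.7
  R <- matrix(lam^2, p, p); diag(R) <- 1
  fit <- fit_efa(R, 1, n_obs = 500)
  expect_lt(max(abs(fit$loadings - lam)), 1e-6)
  expect_lt(max(abs(fit$uniquenesses - (1 - lam^2))), 1e-4)
  # sampled data: mean loading error small at n = 500
  withr::with_seed(31, {
    n <- 500
    f <- rnorm(n)
    x <- outer(f, rep(lam, p)) +
      matrix(rnorm(n * p, 0, sqrt(1 - lam^2)), n, p)
  })
  fs <- fit_efa(cor(x), 1, n_obs = n)
  expect_lt(mean(abs(fs$loadings - lam)), 0.05)
})

test_that("the reproduced correlation matches input within the reported residual", {
  withr::with_seed(32, {
    x <- matrix(rnorm(200 * 9), 200, 9)
    x[, 1:4] <- x[, 1:4] + rnorm(200)
    x[, 5:9] <- x[, 5:9] + rnorm(200)
    R <- cor(x)
  })
  fit <- fit_efa(R, 2, n_obs = 200)
  Sigma <- fit$loadings %*% fit$Phi %*% t(fit$loadings)
  resid <- (R - Sigma)[upper.tri(R)]
  expect_equal(sqrt(mean(resid^2)), fit$fit$rms_residual, tolerance = 1e-10)
  expect_true(all(fit$communalities <= 1 + 1e-6))
})

test_that("oblimin rotation recovers oblique simple structure and factor correlation", {
  L <- cbind(c(rep(0.8, 5), rep(0, 5)), c(rep(0, 5), rep(0.8, 5)))
  Phi <- matrix(c(1, 0.3, 0.3, 1), 2)
  R <- L %*% Phi %*% t(L); diag(R) <- 1
  fit <- fit_efa(R, 2, n_obs = 500)
  # each variable loads ~0.8 on its own factor, ~0 on the other
  own <- apply(abs(fit$loadings), 1, max)
  cross <- apply(abs(fit$loadings), 1, min)
  expect_lt(max(abs(own - 0.8)), 0.01)
  expect_lt(max(cross), 0.01)
  expect_equal(abs(fit$Phi[1, 2]), 0.3, tolerance = 0.01)
})

test_that("factor signs are deterministic and flips reproduce", {
  withr::with_seed(33, {
    x <- matrix(rnorm(120 * 8), 120, 8)
    x[, 1:4] <- x[, 1:4] - 2 * rnorm(120)  # negative-leaning block
    R <- cor(x)
  })
  f1 <- fit_efa(R, 2, n_obs = 120)
  f2 <- fit_efa(R, 2, n_obs = 120)
  expect_identical(f1$loadings, f2$loadings)
  for (j in seq_len(ncol(f1$loadings)))
    expect_gt(f1$loadings[which.max(abs(f1$loadings[, j])), j], 0)
})

test_that("three-cluster synthetic data loads by genomic cluster", {
  sim <- simulate_cohort(default_sim_config(seed = 2024))
  expr <- detection_filter(normalize_global_mean(sim$ct), 30)
  fit <- fit_efa(expr, 3)
  cl <- sim$truth$mirna_cluster[rownames(fit$loadings)]
  keep <- !is.na(cl)
  dom <- fit$dominant[keep]; cl <- cl[keep]
  map <- tapply(dom, cl, function(x)
    as.integer(names(which.max(table(x)))))
  expect_length(unique(map), 3L)
  expect_gte(mean(dom == map[cl]), 0.95)
})

test_that("cluster scores are row means over observed members", {
  m <- matrix(c(1, 2, NA, 5,
                NA, NA, 4, 6,
                3, 1, 2, NA), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:3), c("a1", "a2", "b1", "b2")))
  cmap <- assign_clusters(ann(c("a1", "a2", "b1", "b2"),
                              c("chr1", "chr1", "chr2", "chr2"),
                              c(100, 200, 100, 200)))
  cs <- cluster_scores(expr_from(m), cmap)
  a <- grep("chr1", colnames(cs$scores))
  b <- grep("chr2", colnames(cs$scores))
  expect_equal(unname(cs$scores[, a]), c(1.5, NA, 2))
  expect_equal(unname(cs$n_used[, a]), c(2L, 0L, 2L))
  expect_true(is.na(cs$scores[2, a]))
  expect_equal(unname(cs$scores[, b]), c(5, 5, 2))
  expect_error(cluster_scores(expr_from(m), cmap, "nope"), "unknown cluster")
})

test_that("cluster scores are member-order invariant and linear", {
  withr::with_seed(34, {
    m <- matrix(rnorm(30), 5, 6,
                dimnames = list(paste0("s", 1:5), paste0("m", 1:6)))
  })
  cmap <- assign_clusters(ann(paste0("m", 1:6), rep("chr4", 6),
                              100 * (1:6)))
  base <- cluster_scores(expr_from(m), cmap)
  shuffled <- cluster_scores(expr_from(m[, c(4, 2, 6, 1, 3, 5)]), cmap)
  expect_equal(base$scores, shuffled$scores)
  doubled <- cluster_scores(expr_from(m + m), cmap)
  expect_equal(doubled$scores, 2 * base$scores)
})

test_that("dimension choice arbitration reports both criteria", {
  withr::with_seed(35, {
    n <- 120
    f <- matrix(rnorm(n * 2), n, 2)
    x <- f[, rep(1:2, each = 8)] * 0.75 +
      matrix(rnorm(n * 16, 0, 0.5), n, 16)
  })
  ch <- choose_n_factors(expr_from(scale(x)), n_sim = 100, seed = 9)
  expect_equal(ch$pa$n_factors, 2L)
  expect_true(ch$n_factors %in% 1:3)
  expect_true(all(is.finite(ch$bic)) || ch$n_factors == ch$pa$n_factors)
})
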