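test_that("per-miRNA t-test matches hand computation and handles degeneracy", {
  m <- rbind(matrix(c(1, 2, 3), 3, 2), matrix(c(4, 5, 6), 3, 2))
  dimnames(m) <- list(paste0("s", 1:6), c("shifted", "same"))
  m[, "same"] <- 1
  md <- data.frame(sample_id = paste0("s", 1:6),
                   group = rep(c("term", "PTB"), each = 3))
  res <- per_mirna_ttest(expr_from(m), md)
  row <- res$table[res$table$mirna_id == "shifted", ]
  expect_equal(abs(row$t), 3.674, tolerance = 1e-3)
  expect_equal(row$df, 4)
  expect_equal(row$mean_term, 2)
  expect_equal(row$mean_ptb, 5)
  expect_match(res$table$note[res$table$mirna_id == "same"], "degenerate")

  # identical groups -> t = 0, p = 1
  m2 <- matrix(rep(c(1, 2, 3), 2), 6, 1,
               dimnames = list(paste0("s", 1:6), "m"))
  r2 <- per_mirna_ttest(expr_from(m2), md)
  expect_equal(r2$table$t, 0)
  expect_equal(r2$table$p_value, 1)
})

test_that("per-miRNA t-tests agree with stats::t.test on random instances", {
  withr::with_seed(41, {
    for (rep in 1:10) {
      n <- 16
      m <- matrix(rnorm(n * 3), n, 3,
                  dimnames = list(sprintf("s%02d", 1:n), c("a", "b", "c")))
      m[sample(length(m), 5)] <- NA
      md <- data.frame(sample_id = sprintf("s%02d", 1:n),
                       group = rep(c("term", "PTB"), each = n / 2))
      res <- per_mirna_ttest(expr_from(m), md)$table
      for (j in c("a", "b", "c")) {
        x <- m[1:8, j]; y <- m[9:16, j]
        want <- t.test(x[!is.na(x)], y[!is.na(y)], var.equal = TRUE)
        row <- res[res$mirna_id == j, ]
        expect_equal(row$t, unname(want$statistic), tolerance = 1e-12)
        expect_equal(row$p_value, want$p.value, tolerance = 1e-12)
      }
    }
  })
})

test_that("the global total-expression test uses raw CT means", {
  withr::with_seed(42, {
    m <- matrix(rnorm(40, 30, 2), 10, 4,
                dimnames = list(sprintf("s%02d", 1:10), paste0("m", 1:4)))
  })
  ct <- ct_matrix(m)
  md <- data.frame(sample_id = sprintf("s%02d", 1:10),
                   group = rep(c("term", "PTB"), each = 5))
  expr <- normalize_global_mean(ct)
  res <- per_mirna_ttest(expr, md, ct = ct)
  want <- t.test(rowMeans(m)[1:5], rowMeans(m)[6:10], var.equal = TRUE)
  expect_equal(res$global$t, unname(want$statistic), tolerance = 1e-12)
})

test_that("outcome correlations match a naive oracle and flag significance", {
  x <- c(0.3, -1.2, 0.5, 2.0, -0.4)
  m <- cbind(self = x, other = c(1.4, 0.2, -0.7, 0.9, 1.1))
  rownames(m) <- paste0("s", 1:5)
  md <- data.frame(sample_id = paste0("s", 1:5),
                   group = c("term", "term", "term", "PTB", "PTB"),
                   pair_id = c("p1", "p2", "p3", "p1", "p2"),
                   gestational_age_birth = x,            # identical to `self`
                   birth_weight = c(3000, 2500, 2800, 3300, 2600),
                   head_circumference = c(33, 31, 32, 34, 32))
  oc <- outcome_correlations(expr_from(m), md)
  expect_equal(oc$r_duration[oc$mirna_id == "self"], 1)
  want <- cor.test(m[, "other"], md$birth_weight)
  expect_equal(oc$r_birthweight[oc$mirna_id == "other"],
               unname(want$estimate), tolerance = 1e-12)
  expect_equal(oc$p_birthweight[oc$mirna_id == "other"], want$p.value,
               tolerance = 1e-12)
  expect_equal(oc$sig_duration[oc$mirna_id == "self"], "**")
  # constant outcome -> NA row
  md2 <- md; md2$head_circumference <- 30
  oc2 <- outcome_correlations(expr_from(m), md2)
  expect_true(all(is.na(oc2$r_headcirc)))
})

test_that("noiseless outcomes are recovered exactly by the mixed model", {
  md <- toy_metadata(n_pairs = 10, seed = 6)
  n <- nrow(md)
  withr::with_seed(7, score <- rnorm(n))
  sc <- structure(list(scores = matrix(score, n, 1,
                                       dimnames = list(md$sample_id, "cl")),
                       n_used = NULL, sample_ids = md$sample_id),
                  class = "cluster_scores")
  sex01 <- as.integer(factor(md$fetal_sex)) - 1L
  md$y <- 2 * score + 0.5 * md$bmi - 0.25 * md$gravida +
    1.5 * md$history_ptb + 0.75 * sex01 + 10
  fit <- suppressMessages(fit_mixed_outcome(sc, md, "y"))
  expect_equal(fit$estimate, 2, tolerance = 1e-6)
  expect_equal(fit$z, fit$estimate / fit$std_err)
  expect_equal(fit$ci95_low, fit$estimate - 1.96 * fit$std_err)
})

test_that("zero pair variance reduces the mixed estimate to OLS", {
  # residuals antisymmetric within pairs: between-pair variance is
  # provably below the within-pair variance, so REML estimates the pair
  # variance at the zero boundary and the fixed effect collapses to OLS
  md <- toy_metadata(n_pairs = 12, seed = 8)
  n <- nrow(md)
  withr::with_seed(9, {
    score <- rnorm(n)
    e_half <- rnorm(n / 2)
    md$y <- 1.3 * score + c(e_half, -e_half)
  })
  sc <- structure(list(scores = matrix(score, n, 1,
                                       dimnames = list(md$sample_id, "cl")),
                       n_used = NULL, sample_ids = md$sample_id),
                  class = "cluster_scores")
  fit <- suppressMessages(fit_mixed_outcome(sc, md, "y"))
  expect_match(fit$note, "singular")
  sex01 <- as.integer(factor(md$fetal_sex)) - 1L
  ols <- lm(md$y ~ score + md$bmi + md$gravida + md$history_ptb + sex01)
  expect_equal(fit$estimate, unname(coef(ols)["score"]), tolerance = 1e-6)
})

test_that("separated logistic outcomes surface a warning note instead of failing", {
  md <- toy_metadata(n_pairs = 10, seed = 10)
  n <- nrow(md)
  score <- ifelse(md$group == "PTB", 2, -2)  # perfect separation
  sc <- structure(list(scores = matrix(score, n, 1,
                                       dimnames = list(md$sample_id, "cl")),
                       n_used = NULL, sample_ids = md$sample_id),
                  class = "cluster_scores")
  fit <- suppressWarnings(suppressMessages(
    fit_mixed_outcome(sc, md, "group", family = "logistic")))
  expect_equal(nrow(fit), 1L)
  expect_true(nzchar(fit$note) || fit$degraded)
})

test_that("term-only regression reports the (R2, F, df) tuple and exact fits", {
  md <- toy_metadata(n_pairs = 12, seed = 11)
  n <- nrow(md)
  withr::with_seed(12, score <- rnorm(n))
  sc <- structure(list(scores = matrix(score, n, 1,
                                       dimnames = list(md$sample_id, "c19mc")),
                       n_used = NULL, sample_ids = md$sample_id),
                  class = "cluster_scores")
  res <- term_only_regression(sc, md)
  expect_named(res, c("coefficients", "r_squared", "F", "df1", "df2",
                      "p_value", "n"))
  expect_equal(res$n, 12L)
  expect_equal(res$df2, res$n - res$df1 - 1)
  # outcome identical to one covariate -> R^2 = 1
  md2 <- md
  md2$head_circumference <- md2$gestational_age_birth
  res2 <- suppressWarnings(term_only_regression(sc, md2))
  expect_equal(res2$r_squared, 1, tolerance = 1e-9)
  expect_error(term_only_regression(sc, md[md$group == "PTB", ]),
               ">= 8 term samples")
})
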