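# two tiny clusters for correlation-matrix plumbing
tiny_map <- function() {
  assign_clusters(ann(c("a1", "a2", "b1", "b2", "b3"),
                      c(rep("chrA", 2), rep("chrB", 3)),
                      c(100, 300, 100, 300, 500)))
}

test_that("correlation matrix reproduces exact and hand-computed Pearson r", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 6)
  m <- cbind(a1 = x, a2 = -x, b1 = y, b2 = y + 1, b3 = rev(y))
  rownames(m) <- paste0("s", 1:5)
  gc <- correlation_matrix(expr_from(m), tiny_map(), min_pairs = 2)
  expect_equal(gc$R["a1", "a2"], -1)
  expect_equal(gc$R["b1", "b2"], 1)
  # naive two-pass Pearson oracle
  naive_r <- function(u, v) {
    du <- u - mean(u); dv <- v - mean(v)
    sum(du * dv) / sqrt(sum(du^2) * sum(dv^2))
  }
  expect_equal(gc$R["a1", "b1"], naive_r(x, y), tolerance = 1e-12)
  expect_true(isSymmetric(gc$R))
  expect_equal(unname(diag(gc$R)), rep(1, 5))
})

test_that("correlation matrix handles groups, ordering and min_pairs", {
  withr::with_seed(7, m <- matrix(rnorm(60), 12, 5,
                                  dimnames = list(sprintf("s%02d", 1:12),
                                                  c("a1", "a2", "b1", "b2", "b3"))))
  md <- data.frame(sample_id = sprintf("s%02d", 1:12),
                   group = rep(c("term", "PTB"), each = 6))
  gc <- correlation_matrix(expr_from(m), tiny_map(), md, "term")
  expect_equal(gc$n_nominal, 6L)
  expect_equal(gc$clusters, c("chrA_cluster1", "chrA_cluster1",
                              "chrB_cluster1", "chrB_cluster1",
                              "chrB_cluster1"))
  # sparse overlap drops an entry below min_pairs
  m[1:9, "a1"] <- NA; m[10:12, "b3"] <- NA
  gc2 <- correlation_matrix(expr_from(m), tiny_map(), min_pairs = 3)
  expect_true(is.na(gc2$R["a1", "b3"]))
  expect_error(correlation_matrix(expr_from(m), tiny_map(), md, "PTB",
                                  min_pairs = 2), NA)
  expect_error(correlation_matrix(expr_from(m[1:2, ]), tiny_map()),
               ">= 3 samples")
})

test_that("Jennrich statistic is exactly zero for equal matrices", {
  withr::with_seed(8, {
    for (p in c(2, 4, 6)) {
      x <- matrix(rnorm(50 * p), 50, p)
      R <- cor(x)
      jt <- jennrich_test(R, R, 21, 33)
      expect_equal(jt$chi2, 0, tolerance = 1e-12)
      expect_equal(jt$df, p * (p - 1) / 2)
      expect_equal(jt$p_value, 1)
    }
  })
  # p = 2 equality is size-independent
  R2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(jennrich_test(R2, R2, 10, 400)$chi2, 0, tolerance = 1e-12)
})

test_that("Jennrich test is symmetric under group exchange with equal n", {
  withr::with_seed(9, {
    for (rep in 1:10) {
      p <- sample(2:6, 1)
      R1 <- cor(matrix(rnorm(40 * p), 40, p))
      R2 <- cor(matrix(rnorm(40 * p), 40, p))
      a <- jennrich_test(R1, R2, 30, 30)$chi2
      b <- jennrich_test(R2, R1, 30, 30)$chi2
      expect_equal(a, b, tolerance = 1e-9)
    }
  })
})

test_that("the null Jennrich statistic follows its chi-squared reference", {
  # p = 4 -> df = 6: empirical 95th percentile within 10% of qchisq(.95, 6)
  withr::with_seed(1717, {
    p <- 4; n <- 60
    Sig <- diag(p); Sig[Sig == 0] <- 0.3
    L <- chol(Sig)
    chis <- vapply(seq_len(1000), function(i) {
      R1 <- cor(matrix(rnorm(n * p), n, p) %*% L)
      R2 <- cor(matrix(rnorm(n * p), n, p) %*% L)
      jennrich_test(R1, R2, n, n)$chi2
    }, numeric(1))
  })
  q95 <- unname(stats::quantile(chis, 0.95))
  expect_lt(abs(q95 - qchisq(0.95, 6)) / qchisq(0.95, 6), 0.10)
})

test_that("Jennrich test rejects unusable inputs with diagnostics", {
  R <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_error(jennrich_test(R, diag(3), 10, 10), "same dimension")
  expect_error(jennrich_test(matrix(1, 1, 1), matrix(1, 1, 1), 5, 5),
               "at least 2")
  # rank-1 "correlation" matrix: singular even after repair is attempted
  ones <- matrix(1, 6, 6)
  expect_error(jennrich_test(ones, ones, 4, 4), NA)  # equal -> Z = 0 works
  Rna <- R; Rna[1, 2] <- NA
  expect_error(jennrich_test(Rna, R, 10, 10), "missing")
})

test_that("submatrix coefficient counts match combinatorics (exhaustive k <= 8)", {
  for (kA in 2:8) {
    ids <- c(paste0("a", seq_len(kA)), paste0("b", 1:4))
    gc <- structure(list(
      group = "all", mirna_ids = ids,
      R = {
        R <- diag(length(ids)); R[R == 0] <- 0.2
        dimnames(R) <- list(ids, ids); R
      },
      n_pairs = NULL, n_nominal = 20,
      clusters = c(rep("A", kA), rep("B", 4))),
      class = "group_correlation")
    expect_length(submatrix_coefficients(gc, "A"), kA * (kA - 1) / 2)
    expect_length(submatrix_coefficients(gc, "A", "B"), kA * 4)
  }
  # named examples: 15 members -> 105; 2 members -> 1; 3 x 4 between -> 12
  ids <- c(paste0("c", 1:15), paste0("d", 1:2))
  gc <- structure(list(group = "all", mirna_ids = ids,
                       R = diag(17) + 0.1 - diag(0.1, 17),
                       n_nominal = 21,
                       clusters = c(rep("c19mc", 15), rep("tiny", 2))),
                  class = "group_correlation")
  dimnames(gc$R) <- list(ids, ids)
  expect_length(submatrix_coefficients(gc, "c19mc"), 105L)
  expect_length(submatrix_coefficients(gc, "tiny"), 1L)
  expect_error(submatrix_coefficients(gc, "nope"), "unknown region")
})

test_that("coefficient-set ANOVA equals the squared pooled t statistic", {
  r1 <- c(0.1, 0.2, 0.3); r2 <- c(0.4, 0.5, 0.6)
  cmp <- compare_coefficient_sets(r1, r2)
  tt <- t.test(r1, r2, var.equal = TRUE)
  expect_equal(cmp$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(cmp$df2, 4L)
  expect_equal(cmp$p_value, tt$p.value, tolerance = 1e-12)

  withr::with_seed(10, {
    for (rep in 1:25) {
      k1 <- sample(3:50, 1); k2 <- sample(3:50, 1)
      a <- runif(k1, -0.9, 0.9); b <- runif(k2, -0.9, 0.9)
      cmp <- compare_coefficient_sets(a, b)
      tt <- t.test(a, b, var.equal = TRUE)
      expect_equal(cmp$F, unname(tt$statistic)^2, tolerance = 1e-9)
      expect_equal(cmp$df2, k1 + k2 - 2L)
    }
  })
  # df2 = 88 for two sets of 45 coefficients
  expect_equal(compare_coefficient_sets(runif(45), runif(45))$df2, 88L)
})

test_that("degenerate coefficient sets are reported, not crashed", {
  same <- compare_coefficient_sets(c(0.2, 0.2), c(0.2, 0.2))
  expect_true(is.na(same$F))
  expect_match(same$note, "zero variance")
  ident <- compare_coefficient_sets(c(0.1, 0.3), c(0.1, 0.3))
  expect_equal(ident$F, 0)
  expect_error(compare_coefficient_sets(0.5, c(0.1, 0.2)), ">= 2")
  # fisher transform: means still reported on the r scale
  fz <- compare_coefficient_sets(c(0.1, 0.2, 0.4), c(0.5, 0.6, 0.7),
                                 transform = "fisher_z")
  expect_equal(fz$mean_r_term, mean(c(0.1, 0.2, 0.4)))
})

test_that("compare_groups orchestrates regions, Jennrich and ANOVA", {
  sim <- simulate_cohort(sim_config(n_pairs = 12, seed = 77))
  expr <- detection_filter(normalize_global_mean(sim$ct), 18)
  cmap <- name_clusters(assign_clusters(sim$annotations), sim$locus_labels)
  cmp <- compare_groups(expr, cmap, sim$metadata,
                        regions = c("c19mc", "miR-17/92"))
  expect_s3_class(cmp, "matrix_comparison")
  expect_setequal(cmp$jennrich$region, c("c19mc", "miR-17/92"))
  # within rows + 1 between row
  expect_equal(nrow(cmp$anova), 3L)
  expect_true(all(cmp$anova$df1 == 1L))
  expect_true(all(cmp$anova$p_bonferroni >= cmp$anova$p_value, na.rm = TRUE))
  # generator truth: attenuated PTB within-c14mc loadings lower mean r
  cmp14 <- compare_groups(expr, cmap, sim$metadata, regions = "c14mc")
  within14 <- cmp14$anova[cmp14$anova$regionA == "c14mc" &
                            cmp14$anova$regionB == "c14mc", ]
  expect_gt(within14$mean_r_term, within14$mean_r_ptb)
})

test_that("a two-miRNA region gives Jennrich df = 1", {
  sim <- simulate_cohort(sim_config(
    n_pairs = 10,
    clusters = data.frame(name = c("tiny", "big"),
                          n_mirnas = c(2L, 5L),
                          chromosome = c("chr2", "chr3"),
                          base_position = c(1e6, 2e6),
                          spacing_bp = c(500, 500)),
    loading_scale_ptb = c(tiny = 1, big = 1),
    factor_corr_term = {
      m <- diag(2); dimnames(m) <- list(c("tiny", "big"), c("tiny", "big")); m
    },
    factor_corr_ptb = {
      m <- diag(2); dimnames(m) <- list(c("tiny", "big"), c("tiny", "big")); m
    },
    outcome_betas = c(tiny = 0, big = 0),
    hc_betas = numeric(0),
    n_background = 20, seed = 5))
  expr <- normalize_global_mean(sim$ct)
  cmap <- assign_clusters(sim$annotations)
  tiny_name <- cmap$membership[["sim-mir-tiny-01"]]
  cmp <- compare_groups(expr, cmap, sim$metadata, regions = tiny_name)
  expect_equal(cmp$jennrich$df[cmp$jennrich$region == tiny_name], 1)
})
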