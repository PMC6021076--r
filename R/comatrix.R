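#' Cluster-ordered Pearson correlation matrix for one group
#'
#' Pearson correlations of -dCT values over pairwise-complete
#' observations, with rows/columns restricted to clustered miRNAs and
#' ordered by cluster then genomic position (the order recorded in the
#' `cluster_map`). Entries supported by fewer than `min_pairs` complete
#' pairs are set missing.
#'
#' @param expr an [expression_matrix()].
#' @param cluster_map a `cluster_map`; only member miRNAs present in
#'   `expr` are used.
#' @param metadata optional `sample_metadata` for group selection.
#' @param group `"all"`, `"term"` or `"PTB"` (the latter two need
#'   `metadata`).
#' @param min_pairs minimum pairwise-complete sample count per entry.
#' @return object of class `group_correlation`: `group`, `mirna_ids`,
#'   `R` (correlation matrix), `n_pairs` (pairwise counts), `n_nominal`
#'   (group sample count), `clusters` (name per miRNA).
#' @export
correlation_matrix <- function(expr, cluster_map, metadata = NULL,
                               group = c("all", "term", "PTB"),
                               min_pairs = 10) {
  stopifnot(inherits(expr, "expression_matrix"))
  group <- match.arg(group)
  samples <- expr$sample_ids
  if (group != "all") {
    if (is.null(metadata)) stop("metadata required for group selection")
    samples <- intersect(samples,
                         metadata$sample_id[metadata$group == group])
    if (!length(samples)) stop("no samples match group '", group, "'")
  }
  if (length(samples) < 3L)
    stop("need >= 3 samples for a correlation matrix; got ", length(samples))
  ids <- ordered_members(cluster_map, expr$mirna_ids)
  x <- expr$dct[samples, ids$mirna_id, drop = FALSE]
  obs <- !is.na(x)
  n_pairs <- crossprod(obs)
  R <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  R[n_pairs < min_pairs] <- NA_real_
  diag(R) <- 1
  structure(list(group = group, mirna_ids = ids$mirna_id, R = R,
                 n_pairs = n_pairs, n_nominal = length(samples),
                 clusters = ids$cluster),
            class = "group_correlation")
}

# cluster-ordered member ids restricted to those present in `available`
ordered_members <- function(cluster_map, available) {
  stopifnot(inherits(cluster_map, "cluster_map"))
  ids <- character(0); cl <- character(0)
  for (nm in names(cluster_map$clusters)) {
    mem <- intersect(cluster_map$clusters[[nm]], available)
    ids <- c(ids, mem); cl <- c(cl, rep(nm, length(mem)))
  }
  if (!length(ids)) stop("no clustered miRNAs present in the matrix")
  data.frame(mirna_id = ids, cluster = cl, stringsAsFactors = FALSE)
}

#' @export
print.group_correlation <- function(x, ...) {
  cat(sprintf("group_correlation [%s]: %d miRNAs, n = %d\n",
              x$group, length(x$mirna_ids), x$n_nominal))
  invisible(x)
}

#' Jennrich test for the equality of two correlation matrices
#'
#' Chi-squared test that two correlation matrices estimated from
#' independent samples of sizes n1 and n2 are equal. With the pooled
#' matrix Rbar = (n1 R1 + n2 R2)/(n1 + n2), c = n1 n2/(n1 + n2),
#' Z = sqrt(c) Rbar^{-1} (R1 - R2), and S = I + Rbar * Rbar^{-1}
#' (elementwise product), the statistic is
#' chi2 = tr(Z^2)/2 - diag(Z)' S^{-1} diag(Z) with p(p-1)/2 degrees of
#' freedom for p variables.
#'
#' Inputs must be positive definite; matrices with eigenvalues below
#' `pd_tol` are repaired to the nearest positive-definite correlation
#' matrix (recorded in the result) before testing. A pooled or S matrix
#' with condition number above `max_condition` aborts with diagnostics
#' rather than returning a meaningless statistic.
#'
#' @param R1,R2 correlation matrices of the same dimension p >= 2.
#' @param n1,n2 sample counts behind each matrix.
#' @param pd_tol eigenvalue floor below which a matrix is repaired.
#' @param max_condition condition-number limit for Rbar and S.
#' @return list with `chi2`, `df`, `p_value`, `n1`, `n2`, `p`,
#'   `repaired` (logical: was either input nearest-PD adjusted).
#' @export
jennrich_test <- function(R1, R2, n1, n2, pd_tol = 1e-8,
                          max_condition = 1e10) {
  R1 <- as.matrix(R1); R2 <- as.matrix(R2)
  p <- nrow(R1)
  if (!all(dim(R1) == c(p, p)) || !all(dim(R2) == c(p, p)))
    stop("R1 and R2 must be square matrices of the same dimension")
  if (p < 2L) stop("need at least 2 variables")
  if (anyNA(R1) || anyNA(R2))
    stop("correlation matrices contain missing entries; raise min_pairs ",
         "coverage or subset before testing")
  rep1 <- needs_pd_repair(R1, pd_tol); rep2 <- needs_pd_repair(R2, pd_tol)
  if (rep1) R1 <- repair_pd(R1, pd_tol)
  if (rep2) R2 <- repair_pd(R2, pd_tol)
  Rbar <- (n1 * R1 + n2 * R2) / (n1 + n2)
  kap <- kappa(Rbar, exact = TRUE)
  if (!is.finite(kap) || kap > max_condition)
    stop(sprintf(
      "pooled correlation matrix is numerically singular (condition number %.3g > %.3g); p = %d with n1 = %d, n2 = %d gives no stable Jennrich statistic",
      kap, max_condition, p, n1, n2))
  Rinv <- solve(Rbar)
  cc <- n1 * n2 / (n1 + n2)
  Z <- sqrt(cc) * Rinv %*% (R1 - R2)
  S <- diag(p) + Rbar * Rinv
  kapS <- kappa(S, exact = TRUE)
  if (!is.finite(kapS) || kapS > max_condition)
    stop(sprintf("S matrix numerically singular (condition number %.3g)",
                 kapS))
  dz <- diag(Z)
  chi2 <- 0.5 * sum(diag(Z %*% Z)) - drop(crossprod(dz, solve(S, dz)))
  df <- p * (p - 1) / 2
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
       n1 = n1, n2 = n2, p = p, repaired = rep1 || rep2)
}

needs_pd_repair <- function(R, tol = 1e-8) {
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  min(ev) < tol
}

#' Nearest positive-definite correlation repair
#'
#' Thin wrapper over [Matrix::nearPD()] keeping the unit diagonal. Used
#' before operations that invert a pairwise-complete correlation matrix.
#'
#' @param R symmetric matrix.
#' @param eig_floor minimum eigenvalue enforced.
#' @return repaired matrix.
#' @export
repair_pd <- function(R, eig_floor = 1e-8) {
  out <- Matrix::nearPD(R, corr = TRUE, eig.tol = eig_floor,
                        posd.tol = eig_floor, keepDiag = TRUE)
  as.matrix(out$mat)
}

#' Extract a region's correlation coefficients
#'
#' Within-cluster (`regionB` missing or equal to `regionA`): the strictly
#' upper-triangle coefficients of that cluster's block — k(k-1)/2 values
#' for k members. Between-cluster: all kA x kB coefficients of the
#' cross block. Missing entries (insufficient pairwise coverage) are
#' dropped and counted.
#'
#' @param gc a `group_correlation`.
#' @param regionA,regionB cluster names in the matrix ordering.
#' @return numeric vector of r values, with attributes `n_missing` and
#'   `region`.
#' @export
submatrix_coefficients <- function(gc, regionA, regionB = regionA) {
  stopifnot(inherits(gc, "group_correlation"))
  for (r in unique(c(regionA, regionB)))
    if (!r %in% gc$clusters)
      stop("unknown region '", r, "'; available: ",
           paste(unique(gc$clusters), collapse = ", "))
  ia <- which(gc$clusters == regionA)
  if (identical(regionA, regionB)) {
    block <- gc$R[ia, ia, drop = FALSE]
    vals <- block[upper.tri(block)]
    label <- paste0("within:", regionA)
  } else {
    ib <- which(gc$clusters == regionB)
    vals <- as.vector(gc$R[ia, gc$clusters == regionB, drop = FALSE])
    label <- paste0("between:", regionA, ":", regionB)
  }
  miss <- sum(is.na(vals))
  vals <- vals[!is.na(vals)]
  attr(vals, "n_missing") <- miss
  attr(vals, "region") <- label
  vals
}

#' Compare two sets of correlation coefficients by one-way ANOVA
#'
#' Two-group one-way ANOVA on the coefficient sets (optionally Fisher-z
#' transformed), as used to compare the average within- or
#' between-cluster correlation between term and preterm samples. F has
#' df1 = 1 and df2 = k1 + k2 - 2 and equals the square of the pooled
#' two-sample t statistic. Group means are always reported on the r
#' scale.
#'
#' @param r_term,r_ptb numeric vectors of correlation coefficients
#'   (length >= 2 each).
#' @param transform `"none"` (default: the coefficient sets are treated
#'   as approximately normal) or `"fisher_z"`.
#' @return list with `F`, `df1`, `df2`, `p_value`, `mean_r_term`,
#'   `mean_r_ptb`, `transform`. `F` is `NA` (with `note`) when the pooled
#'   data have zero variance.
#' @export
compare_coefficient_sets <- function(r_term, r_ptb,
                                     transform = c("none", "fisher_z")) {
  transform <- match.arg(transform)
  r_term <- r_term[!is.na(r_term)]; r_ptb <- r_ptb[!is.na(r_ptb)]
  if (length(r_term) < 2L || length(r_ptb) < 2L)
    stop("each coefficient set needs >= 2 values")
  x <- if (transform == "fisher_z") atanh(pmin(pmax(r_term, -1 + 1e-12),
                                               1 - 1e-12)) else r_term
  y <- if (transform == "fisher_z") atanh(pmin(pmax(r_ptb, -1 + 1e-12),
                                               1 - 1e-12)) else r_ptb
  k1 <- length(x); k2 <- length(y)
  df2 <- k1 + k2 - 2L
  grand <- mean(c(x, y))
  ssb <- k1 * (mean(x) - grand)^2 + k2 * (mean(y) - grand)^2
  ssw <- sum((x - mean(x))^2) + sum((y - mean(y))^2)
  out <- list(F = NA_real_, df1 = 1L, df2 = df2, p_value = NA_real_,
              mean_r_term = mean(r_term), mean_r_ptb = mean(r_ptb),
              transform = transform)
  if (ssw <= 0 && ssb <= 0) {
    out$note <- "zero variance in pooled coefficients; F undefined"
    return(out)
  }
  out$F <- (ssb / 1) / (ssw / df2)
  out$p_value <- stats::pf(out$F, 1, df2, lower.tail = FALSE)
  out
}

#' Full two-group correlation-structure comparison
#'
#' Orchestrates the cluster-level machinery: builds term and PTB
#' correlation matrices (cluster-ordered), runs the Jennrich equality
#' test on each requested region's within-cluster submatrix (and
#' optionally the full ordered matrix), and compares every within-region
#' and between-region coefficient set by two-group ANOVA. Jennrich
#' failures on regions whose dimension exceeds the group sample size
#' (numerically singular even after nearest-PD repair) are recorded per
#' region, not fatal. A Bonferroni-adjusted p column is emitted alongside
#' the unadjusted ANOVA p-values for transparency; inference in the
#' source design used unadjusted p.
#'
#' @param expr an [expression_matrix()].
#' @param cluster_map a `cluster_map`.
#' @param metadata `sample_metadata` with term/PTB labels.
#' @param regions cluster names to analyse; default: every cluster
#'   present in `expr` with >= 2 members.
#' @param transform passed to [compare_coefficient_sets()].
#' @param min_pairs passed to [correlation_matrix()].
#' @param full_matrix_jennrich also test the full cluster-ordered matrix.
#' @return object of class `matrix_comparison`: `jennrich` (data.frame:
#'   region, chi2, df, p_value, repaired, note), `anova` (data.frame:
#'   regionA, regionB, F, df1, df2, p_value, p_bonferroni, mean_r_term,
#'   mean_r_ptb, n_term_coef, n_ptb_coef), plus the two
#'   `group_correlation` objects.
#' @export
compare_groups <- function(expr, cluster_map, metadata, regions = NULL,
                           transform = c("none", "fisher_z"),
                           min_pairs = 10, full_matrix_jennrich = FALSE) {
  transform <- match.arg(transform)
  gc_term <- correlation_matrix(expr, cluster_map, metadata, "term",
                                min_pairs = min_pairs)
  gc_ptb <- correlation_matrix(expr, cluster_map, metadata, "PTB",
                               min_pairs = min_pairs)
  if (is.null(regions)) {
    tab <- table(gc_term$clusters)
    regions <- names(tab)[tab >= 2L]
    regions <- regions[order(match(regions, gc_term$clusters))]
  }

  jen <- list()
  test_region <- function(label, idx) {
    res <- tryCatch(
      jennrich_test(sub_or_full(gc_term$R, idx), sub_or_full(gc_ptb$R, idx),
                    gc_term$n_nominal, gc_ptb$n_nominal),
      error = function(e) e)
    if (inherits(res, "error"))
      data.frame(region = label, chi2 = NA_real_, df = NA_real_,
                 p_value = NA_real_, repaired = NA,
                 note = conditionMessage(res), stringsAsFactors = FALSE)
    else
      data.frame(region = label, chi2 = res$chi2, df = res$df,
                 p_value = res$p_value, repaired = res$repaired, note = "",
                 stringsAsFactors = FALSE)
  }
  for (r in regions)
    jen[[r]] <- test_region(r, which(gc_term$clusters == r))
  if (full_matrix_jennrich)
    jen[["full_matrix"]] <- test_region("full_matrix",
                                        seq_along(gc_term$mirna_ids))
  jen <- do.call(rbind, jen)

  pairs <- list()
  for (r in regions) pairs[[length(pairs) + 1L]] <- c(r, r)
  if (length(regions) > 1L)
    for (i in seq_len(length(regions) - 1L))
      for (j in seq((i + 1L), length(regions)))
        pairs[[length(pairs) + 1L]] <- c(regions[i], regions[j])

  rows <- lapply(pairs, function(pr) {
    rt <- submatrix_coefficients(gc_term, pr[1L], pr[2L])
    rp <- submatrix_coefficients(gc_ptb, pr[1L], pr[2L])
    cmp <- tryCatch(compare_coefficient_sets(rt, rp, transform),
                    error = function(e)
                      list(F = NA_real_, df1 = 1L,
                           df2 = length(rt) + length(rp) - 2L,
                           p_value = NA_real_,
                           mean_r_term = mean(rt), mean_r_ptb = mean(rp),
                           note = conditionMessage(e)))
    data.frame(regionA = pr[1L], regionB = pr[2L],
               F = cmp$F, df1 = cmp$df1, df2 = cmp$df2,
               p_value = cmp$p_value,
               mean_r_term = cmp$mean_r_term, mean_r_ptb = cmp$mean_r_ptb,
               n_term_coef = length(rt), n_ptb_coef = length(rp),
               stringsAsFactors = FALSE)
  })
  anova_tab <- do.call(rbind, rows)
  anova_tab$p_bonferroni <- pmin(1, anova_tab$p_value * nrow(anova_tab))
  rownames(jen) <- rownames(anova_tab) <- NULL
  structure(list(jennrich = jen, anova = anova_tab,
                 term = gc_term, ptb = gc_ptb,
                 transform = transform),
            class = "matrix_comparison")
}

sub_or_full <- function(R, idx) R[idx, idx, drop = FALSE]

#' @export
print.matrix_comparison <- function(x, ...) {
  cat("Jennrich tests of correlation-matrix equality (term vs PTB):\n")
  print(x$jennrich, row.names = FALSE)
  cat("\nANOVA on coefficient sets:\n")
  print(x$anova, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a matrix comparison as JSON and TSV
#' @param x a `matrix_comparison`.
#' @param json_path,tsv_path output paths (either may be `NULL`).
#' @export
write_comparison <- function(x, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(x, "matrix_comparison"))
  if (!is.null(json_path))
    jsonlite::write_json(list(jennrich = x$jennrich, anova = x$anova),
                         json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
  if (!is.null(tsv_path))
    utils::write.table(x$anova, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(x)
}

#' Dot-style correlation plot
#'
#' Minimal rendering of a cluster-ordered correlation matrix: one dot per
#' pair, blue for positive r and red for negative, dot area proportional
#' to |r|, with cluster boundaries ruled. Intended as a quick visual
#' check of block structure, not a publication figure.
#'
#' @param gc a `group_correlation`.
#' @param file optional PNG or SVG path; `NULL` draws on the active
#'   device.
#' @param cex_max dot size for |r| = 1.
#' @export
plot_correlation_dots <- function(gc, file = NULL, cex_max = 1.6) {
  stopifnot(inherits(gc, "group_correlation"))
  if (!is.null(file)) {
    if (grepl("\\.svg$", file)) grDevices::svg(file, width = 7, height = 7)
    else grDevices::png(file, width = 900, height = 900, res = 120)
    on.exit(grDevices::dev.off())
  }
  p <- length(gc$mirna_ids)
  graphics::plot(NA, xlim = c(0.5, p + 0.5), ylim = c(p + 0.5, 0.5),
                 asp = 1, axes = FALSE, xlab = "", ylab = "",
                 main = sprintf("Pearson r (-dCT), %s (n = %d)",
                                gc$group, gc$n_nominal))
  idx <- which(upper.tri(gc$R, diag = TRUE), arr.ind = TRUE)
  r <- gc$R[idx]
  ok <- !is.na(r)
  graphics::points(idx[ok, 2L], idx[ok, 1L],
                   pch = 16, cex = cex_max * sqrt(abs(r[ok])),
                   col = ifelse(r[ok] >= 0, "#2166AC", "#B2182B"))
  bounds <- cumsum(rle(gc$clusters)$lengths)
  graphics::abline(h = bounds[-length(bounds)] + 0.5,
                   v = bounds[-length(bounds)] + 0.5, col = "grey70")
  mids <- (c(0, utils::head(bounds, -1)) + bounds) / 2
  graphics::mtext(rle(gc$clusters)$values, side = 3, at = mids, cex = 0.8)
  invisible(gc)
}
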