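#' Pairwise-complete correlation matrix of an expression matrix
#'
#' Convenience used by the factor-analysis stage: Pearson correlations
#' over pairwise-complete observations for all miRNAs, repaired to the
#' nearest positive-definite correlation matrix when pairwise deletion
#' produces indefiniteness.
#'
#' @param expr an [expression_matrix()].
#' @param repair apply nearest-PD repair if needed (default TRUE).
#' @return correlation matrix with attribute `repaired` (logical).
#' @export
expr_correlation <- function(expr, repair = TRUE) {
  stopifnot(inherits(expr, "expression_matrix"))
  R <- suppressWarnings(stats::cor(expr$dct, use = "pairwise.complete.obs"))
  if (anyNA(R))
    stop("correlation matrix has missing entries (no overlapping samples ",
         "for some pair); filter low-detection miRNAs first")
  rep_flag <- FALSE
  if (repair && needs_pd_repair(R)) {
    R <- repair_pd(R)
    rep_flag <- TRUE
  }
  attr(R, "repaired") <- rep_flag
  R
}

#' Restrict an expression matrix to clustered miRNAs in cluster order
#'
#' The factor-analysis stage, like the correlation stage, operates on
#' the clustered panel (the loading tables of this design list exactly
#' the cluster members): background miRNAs inform the global-mean
#' normalisation but not the factor model.
#'
#' @param expr an [expression_matrix()].
#' @param cluster_map a `cluster_map`.
#' @return the restricted [expression_matrix()] (zero-mean check off:
#'   subsetting breaks the global-mean identity by design).
#' @export
restrict_to_clusters <- function(expr, cluster_map) {
  ids <- ordered_members(cluster_map, expr$mirna_ids)
  expression_matrix(expr$dct[, ids$mirna_id, drop = FALSE], check = FALSE)
}

#' Horn's parallel analysis for factor retention
#'
#' Compares the observed eigenvalues of the correlation matrix with the
#' eigenvalue distribution of `n_sim` simulated datasets of independent
#' standard normal deviates with the same dimensions, and suggests
#' retaining as many factors as there are leading observed eigenvalues
#' exceeding their simulated reference (classic Horn: the mean simulated
#' eigenvalue; set `quantile` to e.g. 0.95 for the stricter variant).
#'
#' @param expr an [expression_matrix()], or a correlation matrix with an
#'   `n_obs` argument.
#' @param n_sim number of simulated datasets (>= 50 recommended; fewer
#'   draws warn).
#' @param quantile `NULL` for the mean-eigenvalue rule, else a fraction
#'   in (0, 1).
#' @param seed RNG seed for the simulated datasets (required for
#'   reproducibility).
#' @param n_obs number of observations, only when `expr` is a matrix of
#'   correlations.
#' @return list with `n_factors` (suggested count), `eigenvalues`
#'   (observed), `thresholds` (simulated reference).
#' @export
parallel_analysis <- function(expr, n_sim = 200, quantile = NULL, seed = 1,
                              n_obs = NULL) {
  if (inherits(expr, "expression_matrix")) {
    R <- expr_correlation(expr)
    n <- nrow(expr$dct)
  } else {
    R <- as.matrix(expr)
    n <- n_obs
    if (is.null(n)) stop("n_obs required when passing a correlation matrix")
  }
  p <- ncol(R)
  if (n_sim < 50) warning("n_sim < 50 gives unstable retention thresholds")
  if (!is.null(quantile) && (quantile <= 0 || quantile >= 1))
    stop("quantile must be in (0, 1)")
  obs <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  sim <- withr::with_seed(seed, {
    vapply(seq_len(n_sim), function(i) {
      x <- matrix(stats::rnorm(n * p), n, p)
      eigen(stats::cor(x), symmetric = TRUE, only.values = TRUE)$values
    }, numeric(p))
  })
  thr <- if (is.null(quantile)) rowMeans(sim)
         else apply(sim, 1L, stats::quantile, probs = quantile, names = FALSE)
  # leading run of eigenvalues above threshold (stop at the first failure)
  above <- obs > thr
  n_factors <- if (!above[1L]) 0L else which.min(c(above, FALSE)) - 1L
  list(n_factors = as.integer(n_factors), eigenvalues = obs,
       thresholds = thr)
}

# ULS/minres discrepancy concentrated over uniquenesses: given psi, the
# optimal rank-k loadings come from the top-k eigenpairs of R - diag(psi)
# (negative eigenvalues truncated), leaving f(psi) = sum of the squared
# discarded eigenvalues. Gradient: df/dpsi_j = -2 * sum_{i>k} lambda_i v_ji^2.
minres_objective <- function(psi, R, k) {
  S <- R; diag(S) <- 1 - psi
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  tail_ev <- ev[-seq_len(k)]
  sum(tail_ev^2)
}

minres_gradient <- function(psi, R, k) {
  S <- R; diag(S) <- 1 - psi
  e <- eigen(S, symmetric = TRUE)
  tail_idx <- seq.int(k + 1L, length(psi))
  lam <- e$values[tail_idx]
  V <- e$vectors[, tail_idx, drop = FALSE]
  # d lambda_i / d psi_j = -v_ji^2, so df/dpsi_j = -2 sum_i lambda_i v_ji^2
  -2 * as.vector((V^2) %*% lam)
}

minres_loadings <- function(psi, R, k) {
  S <- R; diag(S) <- 1 - psi
  e <- eigen(S, symmetric = TRUE)
  lam <- pmax(e$values[seq_len(k)], 0)
  L <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam), k)
  dimnames(L) <- list(rownames(R), paste0("F", seq_len(k)))
  L
}

# Oblimin criterion (gamma = 0 is quartimin) and its gradient, for the
# oblique gradient-projection rotation algorithm of Jennrich (2002).
oblimin_criterion <- function(L, gamma = 0) {
  p <- nrow(L); k <- ncol(L)
  L2 <- L^2
  N <- matrix(1, k, k) - diag(k)
  X <- L2 %*% N
  if (gamma != 0) X <- (diag(p) - matrix(gamma / p, p, p)) %*% X
  list(f = sum(L2 * X) / 4, G = L * X)
}

rotate_oblimin <- function(A, gamma = 0, eps = 1e-6, maxit = 500,
                           n_starts = 4) {
  k <- ncol(A)
  if (k < 2L)
    return(list(loadings = A, Phi = diag(1), converged = TRUE, f = 0))
  # the identity start can be a saddle of the criterion for symmetric
  # loading patterns, so take the best of several deterministic starts
  starts <- c(list(diag(k)), withr::with_seed(1844, {
    lapply(seq_len(n_starts - 1L), function(i) {
      X <- matrix(stats::rnorm(k * k), k, k)
      X %*% diag(1 / sqrt(colSums(X^2)))
    })
  }))
  best <- NULL
  for (T0 in starts) {
    cand <- gpa_oblq(A, T0, gamma = gamma, eps = eps, maxit = maxit)
    if (is.null(best) || cand$f < best$f - 1e-12) best <- cand
  }
  dimnames(best$loadings) <- dimnames(A)
  dimnames(best$Phi) <- list(colnames(A), colnames(A))
  best
}

# gradient-projection rotation for one start (Jennrich 2002)
gpa_oblq <- function(A, Tm, gamma = 0, eps = 1e-6, maxit = 500) {
  al <- 1
  Ti <- solve(Tm)
  L <- A %*% t(Ti)
  vg <- oblimin_criterion(L, gamma)
  f <- vg$f
  G <- -t(t(L) %*% vg$G %*% Ti)
  k <- ncol(A)
  converged <- FALSE
  for (iter in seq_len(maxit)) {
    Gp <- G - Tm %*% diag(colSums(Tm * G), k)
    s <- sqrt(sum(Gp^2))
    if (s < eps) { converged <- TRUE; break }
    al <- 2 * al
    for (i in seq_len(30)) {
      X <- Tm - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), k)
      Ti <- solve(Tt)
      L <- A %*% t(Ti)
      vg <- oblimin_criterion(L, gamma)
      if (vg$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tm <- Tt
    f <- vg$f
    G <- -t(t(L) %*% vg$G %*% Ti)
  }
  Phi <- crossprod(Tm)
  list(loadings = L, Phi = Phi, converged = converged, f = f)
}

#' Minimum-residual exploratory factor analysis with oblimin rotation
#'
#' Fits a k-factor model to the (pairwise-complete, PD-repaired)
#' correlation matrix by minimum residual: uniquenesses are optimised so
#' that the rank-k approximation from the leading eigenpairs minimises
#' the squared off-diagonal residuals (the classic ULS/minres
#' equivalence). The unrotated solution is rotated to an oblique simple
#' structure with the oblimin criterion via gradient projection. Factor
#' signs are fixed deterministically: each factor's largest-magnitude
#' loading is made positive.
#'
#' Model comparison uses an approximate likelihood-ratio chi-squared with
#' the Bartlett correction, reported as `BIC = chi2 - df * log(n)` so
#' that lower is better across candidate dimensions.
#'
#' @param expr an [expression_matrix()], or a correlation matrix (then
#'   give `n_obs`).
#' @param n_factors number of factors, >= 1 and < number of miRNAs.
#' @param rotation `"oblimin"` or `"none"`.
#' @param oblimin_gamma oblimin family parameter (0 = quartimin, the
#'   usual default).
#' @param n_obs observations behind a correlation-matrix input.
#' @param maxit optimiser iteration cap.
#' @return object of class `factor_solution`: `loadings` (p x k, oblique
#'   pattern), `Phi` (factor correlations), `uniquenesses`,
#'   `communalities`, `n_factors`, `rotation`, `fit` (list: objective,
#'   rms residual, chi2, df, BIC), `dominant` (factor index of each
#'   variable's largest |loading|), `converged`.
#' @export
fit_efa <- function(expr, n_factors, rotation = c("oblimin", "none"),
                    oblimin_gamma = 0, n_obs = NULL, maxit = 1000) {
  rotation <- match.arg(rotation)
  if (inherits(expr, "expression_matrix")) {
    R <- expr_correlation(expr)
    n <- nrow(expr$dct)
  } else {
    R <- as.matrix(expr)
    n <- n_obs
    if (is.null(n)) stop("n_obs required when passing a correlation matrix")
  }
  p <- ncol(R)
  k <- as.integer(n_factors)
  if (k < 1L || k >= p) stop("n_factors must be in [1, ", p - 1L, "]")

  start <- pmin(pmax(1 - smc(R), 0.05), 0.95)
  opt <- stats::optim(start, minres_objective, gr = minres_gradient,
                      R = R, k = k, method = "L-BFGS-B",
                      lower = 1e-3, upper = 1,
                      control = list(maxit = maxit, factr = 1e4))
  if (opt$convergence != 0 && opt$convergence != 52)
    stop("minres optimisation did not converge (code ", opt$convergence,
         ", ", opt$counts[1L], " evaluations): ", opt$message)
  psi <- opt$par
  A <- minres_loadings(psi, R, k)

  if (rotation == "oblimin" && k >= 2L) {
    rot <- rotate_oblimin(A, gamma = oblimin_gamma)
    L <- rot$loadings; Phi <- rot$Phi; rot_conv <- rot$converged
  } else {
    L <- A; Phi <- diag(k); dimnames(Phi) <- list(colnames(A), colnames(A))
    rot_conv <- TRUE
  }
  # deterministic sign: largest-|loading| entry of each factor positive
  flip <- vapply(seq_len(k), function(j) {
    sign(L[which.max(abs(L[, j])), j])
  }, numeric(1))
  flip[flip == 0] <- 1
  L <- sweep(L, 2L, flip, `*`)
  Phi <- diag(flip, k) %*% Phi %*% diag(flip, k)
  dimnames(Phi) <- list(colnames(L), colnames(L))

  Sigma <- L %*% Phi %*% t(L)
  resid <- R - Sigma
  diag(resid) <- 0
  communality <- diag(Sigma)
  fit <- efa_fit_stats(R, Sigma + diag(psi), n, p, k)
  fit$objective <- opt$value
  fit$rms_residual <- sqrt(mean(resid[upper.tri(resid)]^2))

  structure(list(loadings = L, Phi = Phi, uniquenesses = psi,
                 communalities = communality, n_factors = k,
                 rotation = rotation, fit = fit,
                 dominant = apply(abs(L), 1L, which.max),
                 converged = rot_conv),
            class = "factor_solution")
}

# squared multiple correlations for start values; tolerant of
# near-singular R
smc <- function(R) {
  Ri <- tryCatch(solve(R), error = function(e) solve(R + diag(1e-4, ncol(R))))
  1 - 1 / diag(Ri)
}

efa_fit_stats <- function(R, Sigma, n, p, k) {
  df <- ((p - k)^2 - p - k) / 2
  FF <- tryCatch({
    det_ratio <- determinant(Sigma, logarithm = TRUE)$modulus -
      determinant(R, logarithm = TRUE)$modulus
    as.numeric(det_ratio + sum(diag(R %*% solve(Sigma))) - p)
  }, error = function(e) NA_real_)
  chi2 <- if (is.na(FF) || df <= 0) NA_real_
          else max(0, (n - 1 - (2 * p + 5) / 6 - 2 * k / 3) * FF)
  bic <- if (is.na(chi2)) NA_real_ else chi2 - df * log(n)
  list(chi2 = chi2, df = df, BIC = bic)
}

#' @export
print.factor_solution <- function(x, ...) {
  cat(sprintf("factor_solution: %d factors (%s), %d variables\n",
              x$n_factors, x$rotation, nrow(x$loadings)))
  cat(sprintf("  rms off-diagonal residual %.4f; BIC %.1f\n",
              x$fit$rms_residual,
              if (is.na(x$fit$BIC)) NA else x$fit$BIC))
  invisible(x)
}

#' Choose the factor dimension by parallel analysis arbitrated by BIC
#'
#' Takes the parallel-analysis suggestion k, then compares BIC across
#' {k-1, k, k+1} (within valid bounds) and moves to a neighbour only if
#' its BIC is strictly lower. The likelihood-ratio approximation behind
#' the BIC requires a non-singular correlation matrix, so when there are
#' no more observations than variables the BIC column is reported but
#' does not arbitrate (the parallel-analysis count is used). Both
#' criteria and the decision are returned.
#'
#' @inheritParams parallel_analysis
#' @return list with `n_factors`, `pa` (the parallel-analysis result),
#'   `bic` (named numeric over the candidates).
#' @export
choose_n_factors <- function(expr, n_sim = 200, quantile = NULL, seed = 1,
                             n_obs = NULL) {
  pa <- parallel_analysis(expr, n_sim = n_sim, quantile = quantile,
                          seed = seed, n_obs = n_obs)
  p <- length(pa$eigenvalues)
  n <- if (inherits(expr, "expression_matrix")) nrow(expr$dct) else n_obs
  k0 <- max(1L, pa$n_factors)
  cand <- unique(pmin(pmax(c(k0 - 1L, k0, k0 + 1L), 1L), p - 1L))
  bic <- vapply(cand, function(k) {
    fit <- tryCatch(fit_efa(expr, k, rotation = "none", n_obs = n_obs),
                    error = function(e) NULL)
    if (is.null(fit) || is.na(fit$fit$BIC)) Inf else fit$fit$BIC
  }, numeric(1))
  names(bic) <- cand
  k <- k0
  if (n > p && all(is.finite(bic)))
    k <- as.integer(names(bic)[which.min(bic)])
  list(n_factors = k, pa = pa, bic = bic, bic_arbitrated = n > p)
}

#' Row-mean cluster scores
#'
#' For each sample and each requested cluster: the arithmetic mean of the
#' non-missing -dCT values of that cluster's members, the construction
#' used for cluster factor variables (robust to sporadically undetected
#' miRNAs). The count of contributing members is recorded.
#'
#' @param expr an [expression_matrix()].
#' @param cluster_map a `cluster_map`.
#' @param clusters cluster names; default all.
#' @return object of class `cluster_scores`: `scores` (sample x cluster
#'   matrix, `NA` when no member observed), `n_used` (contributing
#'   counts), `sample_ids`.
#' @export
cluster_scores <- function(expr, cluster_map, clusters = NULL) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(cluster_map, "cluster_map"))
  if (is.null(clusters)) clusters <- names(cluster_map$clusters)
  missing_cl <- setdiff(clusters, names(cluster_map$clusters))
  if (length(missing_cl))
    stop("unknown cluster(s): ", paste(missing_cl, collapse = ", "))
  n <- nrow(expr$dct)
  scores <- matrix(NA_real_, n, length(clusters),
                   dimnames = list(expr$sample_ids, clusters))
  n_used <- matrix(0L, n, length(clusters),
                   dimnames = list(expr$sample_ids, clusters))
  for (j in seq_along(clusters)) {
    mem <- intersect(cluster_map$clusters[[clusters[j]]], expr$mirna_ids)
    if (!length(mem)) next
    block <- expr$dct[, mem, drop = FALSE]
    cnt <- rowSums(!is.na(block))
    mu <- rowMeans(block, na.rm = TRUE)
    mu[cnt == 0L] <- NA_real_
    scores[, j] <- mu
    n_used[, j] <- cnt
  }
  structure(list(scores = scores, n_used = n_used,
                 sample_ids = expr$sample_ids),
            class = "cluster_scores")
}

#' @export
print.cluster_scores <- function(x, ...) {
  cat(sprintf("cluster_scores: %d samples x %d clusters\n",
              nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Write a loadings table (TSV) and cluster scores (CSV)
#'
#' @param fs a `factor_solution`.
#' @param cluster_map optional `cluster_map` used to annotate each miRNA
#'   with its assigned cluster.
#' @param path output TSV path.
#' @export
write_loadings <- function(fs, path, cluster_map = NULL) {
  stopifnot(inherits(fs, "factor_solution"))
  df <- data.frame(mirna_id = rownames(fs$loadings), fs$loadings,
                   check.names = FALSE)
  df$dominant_factor <- colnames(fs$loadings)[fs$dominant]
  if (!is.null(cluster_map))
    df$assigned_cluster <- unname(cluster_map$membership[df$mirna_id])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_loadings
#' @param cs a `cluster_scores`.
#' @export
write_scores <- function(cs, path) {
  stopifnot(inherits(cs, "cluster_scores"))
  df <- data.frame(sample_id = cs$sample_ids, cs$scores, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
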