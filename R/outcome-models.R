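#' Per-miRNA two-group t-tests
#'
#' Compares each miRNA's -dCT between term and PTB samples. Default is
#' the pooled-variance Student t-test; set `welch = TRUE` for unequal
#' variances. Also reports a global test comparing total expression
#' between groups, computed on each sample's mean amplified raw CT when a
#' `ct_matrix` is supplied (the per-sample mean -dCT is identically zero
#' by construction, so it cannot carry a global signal).
#'
#' @param expr an [expression_matrix()].
#' @param metadata `sample_metadata` with `group`.
#' @param welch use Welch's unequal-variance t-test.
#' @param ct optional [ct_matrix()] for the global total-expression test.
#' @return list with `table` (mirna_id, t, df, p_value, mean_term,
#'   mean_ptb, n_term, n_ptb, note) and `global` (t, df, p_value or
#'   `NULL`).
#' @export
per_mirna_ttest <- function(expr, metadata, welch = FALSE, ct = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  idx_t <- expr$sample_ids %in% metadata$sample_id[metadata$group == "term"]
  idx_p <- expr$sample_ids %in% metadata$sample_id[metadata$group == "PTB"]
  rows <- lapply(expr$mirna_ids, function(m) {
    x <- expr$dct[idx_t, m]; x <- x[!is.na(x)]
    y <- expr$dct[idx_p, m]; y <- y[!is.na(y)]
    base <- data.frame(mirna_id = m, t = NA_real_, df = NA_real_,
                       p_value = NA_real_,
                       mean_term = if (length(x)) mean(x) else NA_real_,
                       mean_ptb = if (length(y)) mean(y) else NA_real_,
                       n_term = length(x), n_ptb = length(y), note = "",
                       stringsAsFactors = FALSE)
    if (length(x) < 2L || length(y) < 2L) {
      base$note <- "fewer than 2 observations in a group"
      return(base)
    }
    tt <- tryCatch(stats::t.test(x, y, var.equal = !welch),
                   error = function(e) NULL)
    if (is.null(tt)) {
      base$note <- "degenerate data (zero variance)"
      return(base)
    }
    base$t <- unname(tt$statistic); base$df <- unname(tt$parameter)
    base$p_value <- tt$p.value
    base
  })
  tab <- do.call(rbind, rows)
  global <- NULL
  if (!is.null(ct)) {
    tot <- rowMeans(ct$ct, na.rm = TRUE)
    g <- metadata$group[match(ct$sample_ids, metadata$sample_id)]
    gt <- stats::t.test(tot[g == "term"], tot[g == "PTB"],
                        var.equal = !welch)
    global <- list(t = unname(gt$statistic), df = unname(gt$parameter),
                   p_value = gt$p.value)
  }
  list(table = tab, global = global)
}

#' Correlations of individual miRNAs with birth outcomes
#'
#' Pearson correlation of each miRNA's -dCT with pregnancy duration,
#' birth weight and infant head circumference over pairwise-complete
#' samples, with two-sided p-values and significance flags at 0.05 and
#' 0.01 (unadjusted, as conventionally reported). Benjamini-Hochberg
#' q-values per outcome are added for transparency.
#'
#' @param expr an [expression_matrix()].
#' @param metadata `sample_metadata` with outcome columns.
#' @param cluster_map optional `cluster_map` to label each miRNA.
#' @param outcomes named character vector: column name per reported
#'   outcome.
#' @return data.frame with one row per miRNA: cluster, and per outcome
#'   `r_<name>`, `p_<name>`, `sig_<name>` ("", "*", "**"), `q_<name>`.
#' @export
outcome_correlations <- function(expr, metadata, cluster_map = NULL,
                                 outcomes = c(
                                   duration = "gestational_age_birth",
                                   birthweight = "birth_weight",
                                   headcirc = "head_circumference")) {
  stopifnot(inherits(expr, "expression_matrix"))
  miss <- setdiff(unname(outcomes), names(metadata))
  if (length(miss)) stop("metadata missing outcome column(s): ",
                         paste(miss, collapse = ", "))
  md <- metadata[match(expr$sample_ids, metadata$sample_id), ]
  out <- data.frame(mirna_id = expr$mirna_ids, stringsAsFactors = FALSE)
  out$cluster <- if (is.null(cluster_map)) NA_character_
                 else unname(cluster_map$membership[expr$mirna_ids])
  for (nm in names(outcomes)) {
    y <- md[[outcomes[[nm]]]]
    rs <- ps <- rep(NA_real_, ncol(expr$dct))
    if (stats::var(y, na.rm = TRUE) > 0) {
      for (j in seq_along(expr$mirna_ids)) {
        x <- expr$dct[, j]
        ok <- !is.na(x) & !is.na(y)
        if (sum(ok) >= 3L && stats::var(x[ok]) > 0) {
          ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
          rs[j] <- unname(ct$estimate); ps[j] <- ct$p.value
        }
      }
    }
    out[[paste0("r_", nm)]] <- rs
    out[[paste0("p_", nm)]] <- ps
    out[[paste0("sig_", nm)]] <-
      ifelse(is.na(ps), "", ifelse(ps < 0.01, "**",
                                   ifelse(ps < 0.05, "*", "")))
    out[[paste0("q_", nm)]] <- stats::p.adjust(ps, method = "BH")
  }
  out
}

#' Matched-pair mixed-effects regression of an outcome on a cluster score
#'
#' Fits `outcome ~ score + bmi + gravida + history_ptb + fetal_sex` with a
#' random intercept per matched pair, one model per cluster (clusters
#' entered separately). Linear models use `lme4::lmer` (REML); the PTB
#' indicator uses `lme4::glmer` with a logit link. Inference on the
#' cluster term uses the Wald z statistic with a normal 95% CI
#' (`estimate +/- 1.96 se`), the convention for this design. If the
#' random-effects fit fails, the model falls back to fixed effects only
#' and the result is flagged `degraded = TRUE`; a singular (zero
#' pair-variance) fit is retained and noted.
#'
#' @param scores a [cluster_scores()].
#' @param metadata `sample_metadata` with `pair_id`, the outcome and the
#'   covariates.
#' @param outcome metadata column to model, or `"group"` for the
#'   logistic PTB model.
#' @param family `"linear"` or `"logistic"`; default chosen from the
#'   outcome.
#' @param clusters subset of score columns; default all.
#' @param covariates covariate column names included as fixed effects
#'   (missing columns are dropped with a warning).
#' @return data.frame of class `outcome_model_result`, one row per
#'   cluster: estimate, std_err, z, ci95_low, ci95_high, p_value,
#'   n_samples, n_pairs, degraded, note; attribute `covariates_used`.
#' @export
fit_mixed_outcome <- function(scores, metadata, outcome,
                              family = NULL, clusters = NULL,
                              covariates = c("bmi", "gravida",
                                             "history_ptb", "fetal_sex")) {
  stopifnot(inherits(scores, "cluster_scores"))
  if (is.null(family))
    family <- if (identical(outcome, "group")) "logistic" else "linear"
  family <- match.arg(family, c("linear", "logistic"))
  if (is.null(clusters)) clusters <- colnames(scores$scores)
  md <- metadata[match(scores$sample_ids, metadata$sample_id), ]
  if (anyNA(md$sample_id))
    stop("metadata missing for sample(s): ",
         paste(scores$sample_ids[is.na(md$sample_id)], collapse = ", "))
  have <- covariates %in% names(md)
  if (!all(have)) {
    warning("covariate(s) not in metadata, dropped: ",
            paste(covariates[!have], collapse = ", "))
    covariates <- covariates[have]
  }
  y <- if (identical(outcome, "group")) as.integer(md$group == "PTB")
       else md[[outcome]]
  if (is.null(y)) stop("outcome column '", outcome, "' not in metadata")

  rows <- lapply(clusters, function(cl) {
    dat <- data.frame(.y = y, .score = scores$scores[, cl],
                      pair_id = factor(md$pair_id))
    for (cv in covariates) {
      v <- md[[cv]]
      if (is.character(v) || is.factor(v)) v <- as.integer(factor(v)) - 1L
      dat[[cv]] <- as.numeric(v)
    }
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    fixed <- paste(c(".score", covariates), collapse = " + ")
    fml <- stats::as.formula(paste(".y ~", fixed, "+ (1 | pair_id)"))
    fml_fix <- stats::as.formula(paste(".y ~", fixed))
    degraded <- FALSE; notes <- character(0)
    # keep fits that only warn (convergence / separation messages are
    # recorded in `note`); fall back to fixed effects only on hard error
    fit <- withCallingHandlers(
      tryCatch({
        if (family == "linear")
          lme4::lmer(fml, data = dat,
                     control = lme4::lmerControl(
                       check.conv.singular = "ignore"))
        else
          lme4::glmer(fml, data = dat, family = stats::binomial(),
                      control = lme4::glmerControl(
                        check.conv.singular = "ignore"))
      }, error = function(e) e),
      warning = function(w) {
        notes <<- c(notes, trimws(conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    if (inherits(fit, "error")) {
      degraded <- TRUE
      notes <- c(notes, paste0("mixed fit failed (",
                               trimws(conditionMessage(fit)),
                               "); fixed-effects fallback"))
      fit <- if (family == "linear") stats::lm(fml_fix, data = dat)
             else stats::glm(fml_fix, data = dat,
                             family = stats::binomial())
    } else if (lme4::isSingular(fit)) {
      notes <- c(notes, "singular random-effects fit (pair variance ~ 0)")
    }
    note <- paste(unique(notes), collapse = "; ")
    cf <- if (inherits(fit, "merMod"))
      lme4::fixef(fit) else stats::coef(fit)
    vc <- as.matrix(stats::vcov(fit))
    est <- unname(cf[".score"])
    se <- sqrt(vc[".score", ".score"])
    z <- est / se
    data.frame(outcome = if (identical(outcome, "group")) "PTB_status"
                         else outcome,
               cluster = cl, estimate = est, std_err = se, z = z,
               ci95_low = est - 1.96 * se, ci95_high = est + 1.96 * se,
               p_value = 2 * stats::pnorm(-abs(z)),
               n_samples = nrow(dat),
               n_pairs = length(unique(dat$pair_id)),
               degraded = degraded, note = note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "covariates_used") <- covariates
  attr(out, "family") <- family
  class(out) <- c("outcome_model_result", "data.frame")
  out
}

#' Ordinary regression on the term-delivery subset
#'
#' Linear model of one outcome on a cluster score plus covariates using
#' term samples only — used to ask whether a cluster/outcome association
#' (e.g. c19mc and head circumference) persists independently of
#' gestational age and birth weight within term deliveries. Reports the
#' coefficient table, R-squared and the overall F test in the
#' conventional `(R^2, F(df1, df2), p)` form.
#'
#' @param scores a [cluster_scores()].
#' @param metadata `sample_metadata`.
#' @param outcome metadata outcome column (default head circumference).
#' @param cluster score column to use.
#' @param covariates additional fixed covariates.
#' @param extra_covariates outcome-scale covariates added for the
#'   independence question (default gestational age and birth weight).
#' @return list with `coefficients` (data.frame), `r_squared`, `F`,
#'   `df1`, `df2`, `p_value`, `n`.
#' @export
term_only_regression <- function(scores, metadata,
                                 outcome = "head_circumference",
                                 cluster = "c19mc",
                                 covariates = c("bmi", "gravida",
                                                "history_ptb", "fetal_sex"),
                                 extra_covariates = c(
                                   "gestational_age_birth",
                                   "birth_weight")) {
  stopifnot(inherits(scores, "cluster_scores"))
  md <- metadata[match(scores$sample_ids, metadata$sample_id), ]
  keep <- md$group == "term"
  if (sum(keep, na.rm = TRUE) < 8L)
    stop("need >= 8 term samples; have ", sum(keep, na.rm = TRUE))
  covs <- intersect(c(covariates, extra_covariates), names(md))
  dat <- data.frame(.y = md[[outcome]][keep],
                    .score = scores$scores[keep, cluster])
  for (cv in covs) {
    v <- md[[cv]][keep]
    if (is.character(v) || is.factor(v)) v <- as.integer(factor(v)) - 1L
    dat[[cv]] <- as.numeric(v)
  }
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  fml <- stats::as.formula(paste(".y ~ .score +",
                                 paste(covs, collapse = " + ")))
  fit <- stats::lm(fml, data = dat)
  alias <- stats::alias(fit)$Complete
  if (!is.null(alias))
    stop("rank-deficient design; collinear column(s): ",
         paste(rownames(alias), collapse = ", "))
  sm <- summary(fit)
  co <- as.data.frame(sm$coefficients)
  names(co) <- c("estimate", "std_err", "t", "p_value")
  co$term <- rownames(co); rownames(co) <- NULL
  fstat <- sm$fstatistic
  list(coefficients = co[, c("term", "estimate", "std_err", "t", "p_value")],
       r_squared = unname(sm$r.squared),
       F = unname(fstat[1L]), df1 = unname(fstat[2L]),
       df2 = unname(fstat[3L]),
       p_value = stats::pf(fstat[1L], fstat[2L], fstat[3L],
                           lower.tail = FALSE),
       n = nrow(dat))
}
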