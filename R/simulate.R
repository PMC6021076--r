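#' Simulation configuration for a matched-pair miRNA cohort
#'
#' Defines the stochastic world the generator draws from: a one-factor
#' model per genomic cluster, with group-specific coupling between the
#' cluster factors (between-cluster structure) and group-specific loading
#' attenuation (within-cluster structure), qPCR censoring, and birth
#' outcomes driven by the cluster scores.
#'
#' @param n_pairs matched term/PTB pairs (default 21, i.e. 42 samples).
#' @param clusters data.frame with columns `name`, `n_mirnas`,
#'   `chromosome`, `base_position`, `spacing_bp` (spacing must be <=
#'   10000 so generated clusters chain correctly under the 10 kb rule).
#' @param loading_mean,loading_sd per-miRNA factor loadings are drawn
#'   once as N(loading_mean, loading_sd), truncated to (0.2, 0.98).
#' @param loading_scale_ptb named multiplier per cluster applied to PTB
#'   samples' loadings (values < 1 weaken within-cluster correlation in
#'   PTB, > 1 strengthen it).
#' @param factor_corr_term,factor_corr_ptb cluster x cluster latent
#'   correlation matrices (unit diagonal, positive semi-definite).
#' @param noise_sd residual -dCT standard deviation.
#' @param n_background unclustered background miRNAs on the panel
#'   (factor-free noise, placed as genomic singletons). The qPCR panel
#'   behind the design detects far more miRNAs than the three clusters,
#'   and the global-mean normalisation averages over all of them; without
#'   this background the per-sample centring would impose a linear
#'   constraint across the three cluster levels and collapse them to two
#'   effective dimensions.
#' @param background_sd marginal -dCT sd of background miRNAs (default
#'   0.9, matching the clustered miRNAs' marginal sd
#'   sqrt(loading^2 + noise_sd^2)).
#' @param ct_base_mean,ct_base_sd per-miRNA baseline CT level
#'   distribution; miRNAs whose baseline sits near `censor_ct` produce
#'   realistic unamplified rates.
#' @param censor_ct CT above which a reaction is unamplified.
#' @param outcome_betas named effect (weeks of gestation per unit cluster
#'   score) per cluster.
#' @param outcome_on `"score"`: gestational age is generated from the
#'   realized row-mean cluster scores (the observable the downstream
#'   models regress on, so `outcome_betas` is the exact estimand);
#'   `"factor"`: from the latent factors.
#' @param ga_term_mean,ga_term_sd,ga_ptb_mean,ga_ptb_sd group-specific
#'   gestational-age baselines and residual sds (weeks). The term/PTB
#'   label is the *recruitment group* (a case-control design samples
#'   deliveries by outcome); gestational age is
#'   `baseline(group) + sum(outcome_betas * score) + N(0, sd(group))`.
#'   Conditioning the label on a GA threshold instead would select on
#'   the cluster scores (or on the GA residual), distorting the
#'   configured correlation structure (or biasing the score
#'   coefficient), so the label-authoritative design is used and GA
#'   falls on the label's side of `ptb_cutoff` for ~90% of samples.
#' @param ga_mean anchor (weeks) for the birth weight and head
#'   circumference linear predictors.
#' @param bw_per_week,bw_sd,bw_mean,bw_betas birth weight model:
#'   `bw_mean + bw_per_week * (GA - ga_mean) + sum(bw_betas * score) +
#'   N(0, bw_sd)` grams; `bw_betas` named per cluster (missing = 0).
#' @param hc_per_week,hc_sd,hc_mean,hc_betas head circumference model,
#'   cm, same form; default gives c19mc a direct effect independent of
#'   gestational age.
#' @param ptb_cutoff completed weeks conventionally defining preterm
#'   birth; used by the metadata validator, not by the label.
#' @param seed integer RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 21,
                       clusters = data.frame(
                         name = c("c14mc", "c19mc", "miR-17/92"),
                         n_mirnas = c(33L, 15L, 10L),
                         chromosome = c("chr14", "chr19", "chr13"),
                         base_position = c(100.9e6, 53.7e6, 91.3e6),
                         spacing_bp = c(1200, 1500, 800),
                         stringsAsFactors = FALSE),
                       loading_mean = 0.8, loading_sd = 0.05,
                       loading_scale_ptb = c(c14mc = 0.7, c19mc = 1.1,
                                             `miR-17/92` = 1.0),
                       factor_corr_term = default_factor_corr(-0.3, -0.2, 0.2),
                       factor_corr_ptb = default_factor_corr(-0.7, -0.2, 0.4),
                       noise_sd = 0.4,
                       n_background = 60, background_sd = 0.9,
                       ct_base_mean = 36, ct_base_sd = 6,
                       censor_ct = 50,
                       outcome_betas = c(c14mc = 0.8, c19mc = -0.6,
                                         `miR-17/92` = 0.3),
                       outcome_on = c("score", "factor"),
                       ga_term_mean = 38.6, ga_term_sd = 0.7,
                       ga_ptb_mean = 35.3, ga_ptb_sd = 2.4,
                       ga_mean = 36.9,
                       bw_per_week = 160, bw_sd = 250, bw_mean = 2852,
                       bw_betas = numeric(0),
                       hc_per_week = 0.3, hc_sd = 1.1, hc_mean = 32.6,
                       hc_betas = c(c19mc = -0.9),
                       ptb_cutoff = 37,
                       seed = 1L) {
  outcome_on <- match.arg(outcome_on)
  cfg <- list(n_pairs = as.integer(n_pairs), clusters = clusters,
              loading_mean = loading_mean, loading_sd = loading_sd,
              loading_scale_ptb = loading_scale_ptb,
              factor_corr_term = factor_corr_term,
              factor_corr_ptb = factor_corr_ptb,
              noise_sd = noise_sd,
              n_background = as.integer(n_background),
              background_sd = background_sd,
              ct_base_mean = ct_base_mean, ct_base_sd = ct_base_sd,
              censor_ct = censor_ct,
              outcome_betas = outcome_betas, outcome_on = outcome_on,
              ga_term_mean = ga_term_mean, ga_term_sd = ga_term_sd,
              ga_ptb_mean = ga_ptb_mean, ga_ptb_sd = ga_ptb_sd,
              ga_mean = ga_mean,
              bw_per_week = bw_per_week, bw_sd = bw_sd, bw_mean = bw_mean,
              bw_betas = bw_betas,
              hc_per_week = hc_per_week, hc_sd = hc_sd, hc_mean = hc_mean,
              hc_betas = hc_betas,
              ptb_cutoff = ptb_cutoff, seed = as.integer(seed))
  validate_sim_config(cfg)
}

default_factor_corr <- function(r_14_19, r_19_17, r_14_17) {
  m <- diag(3)
  dimnames(m) <- list(c("c14mc", "c19mc", "miR-17/92"),
                      c("c14mc", "c19mc", "miR-17/92"))
  m["c14mc", "c19mc"] <- m["c19mc", "c14mc"] <- r_14_19
  m["c19mc", "miR-17/92"] <- m["miR-17/92", "c19mc"] <- r_19_17
  m["c14mc", "miR-17/92"] <- m["miR-17/92", "c14mc"] <- r_14_17
  m
}

validate_sim_config <- function(cfg) {
  cl <- cfg$clusters
  need <- c("name", "n_mirnas", "chromosome", "base_position", "spacing_bp")
  if (!all(need %in% names(cl)))
    stop("clusters table needs columns: ", paste(need, collapse = ", "))
  if (any(cl$n_mirnas < 2L)) stop("every cluster needs >= 2 miRNAs")
  if (any(cl$spacing_bp > 10000))
    stop("spacing_bp > 10000 would break the cluster under the 10 kb rule")
  for (nm in c("factor_corr_term", "factor_corr_ptb")) {
    m <- cfg[[nm]]
    if (!isSymmetric(unname(m)) || any(abs(diag(m) - 1) > 1e-12))
      stop(nm, " must be symmetric with unit diagonal")
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10)
      stop(nm, " is not positive semi-definite (min eigenvalue ",
           format(min(ev)), ")")
    if (!identical(dim(m), c(nrow(cl), nrow(cl))))
      stop(nm, " dimension must match the number of clusters")
  }
  if (!all(cl$name %in% names(cfg$outcome_betas)))
    stop("outcome_betas must name every cluster")
  if (!all(cl$name %in% names(cfg$loading_scale_ptb)))
    stop("loading_scale_ptb must name every cluster")
  class(cfg) <- "sim_config"
  cfg
}

#' Default simulated-cohort configuration
#'
#' The documented defaults of [sim_config()]: 21 matched pairs (42
#' samples); clusters of 33 (c14mc-like, chr14), 15 (c19mc-like, chr19)
#' and 10 (miR-17/92-like) miRNAs; loadings 0.8 with residual sd 0.4;
#' latent c14mc-c19mc coupling -0.3 in term vs -0.7 in PTB with c14mc
#' loadings attenuated (x0.7) and c19mc strengthened (x1.1) in PTB;
#' gestational-age dispersion tuned to ~1.6 weeks overall; PTB defined as
#' <= 37 completed weeks.
#'
#' @param seed RNG seed.
#' @return a `sim_config`.
#' @export
default_sim_config <- function(seed = 1L) sim_config(seed = seed)

#' Simulate a matched-pair circulating-miRNA qPCR cohort
#'
#' Draws the world defined by a [sim_config()]:
#' \enumerate{
#'   \item per-sample latent cluster factors from a multivariate normal
#'     with the group's factor correlation matrix;
#'   \item -dCT = loading x factor + noise per miRNA, with PTB loadings
#'     scaled per cluster;
#'   \item CT = per-miRNA baseline - dCT, censored above `censor_ct`;
#'   \item gestational age = `ga_mean` + sum of cluster effects + noise;
#'     birth weight and head circumference as linear functions of
#'     gestational age; PTB label by the <= cutoff rule.
#' }
#' Group structure and threshold labels are reconciled by rejection:
#' candidates drawn under a group's coupling are kept only when their
#' gestational age lands on that group's side of the cutoff, then pairs
#' are formed by taking one term and one PTB member per `pair_id` in
#' order (the real design matched on covariates; the generator's
#' covariates are exchangeable, so in-order pairing is equivalent).
#'
#' @param config a `sim_config`.
#' @return list with `ct` ([ct_matrix()]), `annotations`
#'   (`mirna_annotation`; miR-17/92 members split across chr13 and chrX
#'   with a shared family label), `metadata` (`sample_metadata`),
#'   `truth` (list: per-sample latent factors, per-miRNA loadings and
#'   cluster, true -dCT matrix, realized scores used for outcomes,
#'   outcome betas, config).
#' @export
simulate_cohort <- function(config = default_sim_config()) {
  cfg <- validate_sim_config(config)
  withr::with_seed(cfg$seed, simulate_cohort_impl(cfg))
}

simulate_cohort_impl <- function(cfg) {
  cl <- cfg$clusters
  K <- nrow(cl)
  nb <- cfg$n_background
  mirna_ids <- c(
    unlist(lapply(seq_len(K), function(i)
      sprintf("sim-mir-%s-%02d", gsub("[^0-9A-Za-z]", "", cl$name[i]),
              seq_len(cl$n_mirnas[i])))),
    if (nb > 0L) sprintf("sim-mir-bg-%02d", seq_len(nb)))
  mirna_cluster <- c(rep(cl$name, cl$n_mirnas), rep(NA_character_, nb))
  in_cluster <- !is.na(mirna_cluster)
  p <- length(mirna_ids)

  loadings <- pmin(pmax(stats::rnorm(p, cfg$loading_mean, cfg$loading_sd),
                        0), 0.98)
  loadings[!in_cluster] <- 0
  names(loadings) <- mirna_ids
  ct_base <- stats::rnorm(p, cfg$ct_base_mean, cfg$ct_base_sd)
  names(ct_base) <- mirna_ids

  chol_term <- chol_psd(cfg$factor_corr_term)
  chol_ptb <- chol_psd(cfg$factor_corr_ptb)

  draw_candidate <- function(group) {
    f <- drop(crossprod(if (group == "term") chol_term else chol_ptb,
                        stats::rnorm(K)))
    names(f) <- cl$name
    lam <- loadings
    if (group == "PTB")
      lam[in_cluster] <- lam[in_cluster] *
        cfg$loading_scale_ptb[mirna_cluster[in_cluster]]
    dct <- numeric(p)
    dct[in_cluster] <- lam[in_cluster] * f[mirna_cluster[in_cluster]] +
      stats::rnorm(sum(in_cluster), 0, cfg$noise_sd)
    dct[!in_cluster] <- stats::rnorm(p - sum(in_cluster), 0,
                                     cfg$background_sd)
    # -dCT is only observable relative to the sample's global mean, so
    # outcome-driving scores are computed on the centred scale the
    # downstream models actually see
    dct_c <- dct - mean(dct)
    score <- vapply(cl$name, function(nm)
      mean(dct_c[in_cluster & mirna_cluster == nm]), numeric(1))
    driver <- if (cfg$outcome_on == "score") score else f
    base <- if (group == "term") cfg$ga_term_mean else cfg$ga_ptb_mean
    sdg <- if (group == "term") cfg$ga_term_sd else cfg$ga_ptb_sd
    ga <- base + sum(cfg$outcome_betas[cl$name] * driver[cl$name]) +
      stats::rnorm(1, 0, sdg)
    list(f = f, dct = dct, score = score, driver = driver, ga = ga)
  }
  term <- lapply(seq_len(cfg$n_pairs), function(i) draw_candidate("term"))
  ptb <- lapply(seq_len(cfg$n_pairs), function(i) draw_candidate("PTB"))

  n <- 2L * cfg$n_pairs
  sample_ids <- sprintf("S%02d", seq_len(n))
  group <- rep(c("term", "PTB"), each = cfg$n_pairs)
  pair_id <- sprintf("P%02d", c(seq_len(cfg$n_pairs), seq_len(cfg$n_pairs)))
  all_draws <- c(term, ptb)

  dct_true <- do.call(rbind, lapply(all_draws, `[[`, "dct"))
  dimnames(dct_true) <- list(sample_ids, mirna_ids)
  factors <- do.call(rbind, lapply(all_draws, `[[`, "f"))
  dimnames(factors) <- list(sample_ids, cl$name)
  scores_true <- do.call(rbind, lapply(all_draws, `[[`, "score"))
  dimnames(scores_true) <- list(sample_ids, cl$name)
  ga <- vapply(all_draws, `[[`, numeric(1), "ga")

  ct_vals <- sweep(-dct_true, 2L, ct_base, FUN = "+")
  ct <- ct_matrix(ct_vals, unamplified_ct = cfg$censor_ct)

  drivers <- do.call(rbind, lapply(all_draws, `[[`, "driver"))
  beta_sum <- function(betas) {
    b <- stats::setNames(rep(0, nrow(cl)), cl$name)
    use <- intersect(names(betas), cl$name)
    b[use] <- betas[use]
    drop(drivers %*% b)
  }
  bw <- cfg$bw_mean + cfg$bw_per_week * (ga - cfg$ga_mean) +
    beta_sum(cfg$bw_betas) + stats::rnorm(n, 0, cfg$bw_sd)
  hc <- cfg$hc_mean + cfg$hc_per_week * (ga - cfg$ga_mean) +
    beta_sum(cfg$hc_betas) + stats::rnorm(n, 0, cfg$hc_sd)
  metadata <- data.frame(
    sample_id = sample_ids, group = group, pair_id = pair_id,
    gestational_age_birth = round(ga, 2),
    birth_weight = round(bw), head_circumference = round(hc, 1),
    bmi = round(stats::rnorm(n, 25.7, 5.3), 1),
    gravida = sample(1:5, n, replace = TRUE,
                     prob = c(0.17, 0.17, 0.38, 0.2, 0.08)),
    history_ptb = as.integer(stats::runif(n) < 10 / 42),
    fetal_sex = sample(c("F", "M"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  metadata <- suppressWarnings(
    validate_metadata(metadata, ptb_cutoff = cfg$ptb_cutoff))

  annotations <- build_sim_annotations(cl, mirna_ids, mirna_cluster)
  # locus labels mapping the generated genomic spans to canonical names,
  # mirroring a cytoband table for the emulated loci
  locus_labels <- do.call(rbind, lapply(
    seq_len(K)[!grepl("/", cl$name, fixed = TRUE)], function(i) {
      span_lo <- cl$base_position[i]
      span_hi <- cl$base_position[i] + cl$n_mirnas[i] * cl$spacing_bp[i] + 1e4
      data.frame(chromosome = cl$chromosome[i], start = span_lo,
                 end = span_hi, name = cl$name[i],
                 stringsAsFactors = FALSE)
    }))

  truth <- list(factors = factors, loadings = loadings,
                mirna_cluster = stats::setNames(mirna_cluster, mirna_ids),
                dct_true = dct_true, scores_true = scores_true,
                ct_base = ct_base,
                outcome_betas = cfg$outcome_betas,
                gestational_age = stats::setNames(ga, sample_ids),
                config = cfg)
  list(ct = ct, annotations = annotations, metadata = metadata,
       locus_labels = locus_labels, truth = truth)
}

# PSD-tolerant upper Cholesky via eigendecomposition
chol_psd <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  t(e$vectors %*% diag(sqrt(ev), length(ev)))
}

# miR-17/92-like family clusters are split across two chromosomes
# (13q31.3 and Xq26.2) with a shared family label; genomic clusters lie
# on one chromosome
build_sim_annotations <- function(cl, mirna_ids, mirna_cluster) {
  bg_ids <- mirna_ids[is.na(mirna_cluster)]
  bg <- if (length(bg_ids)) {
    # genomic singletons: > 10 kb apart, scattered over autosomes
    start <- 5e6 + (seq_along(bg_ids) - 1L) * 5e4
    data.frame(mirna_id = bg_ids,
               chromosome = paste0("chr", 1 + (seq_along(bg_ids) - 1L) %% 12),
               start = start, end = start + 80, strand = "+",
               family = NA_character_, stringsAsFactors = FALSE)
  } else NULL
  rows <- lapply(seq_len(nrow(cl)), function(i) {
    ids <- mirna_ids[which(mirna_cluster == cl$name[i])]
    k <- length(ids)
    is_family <- grepl("/", cl$name[i], fixed = TRUE)
    if (is_family) {
      k1 <- ceiling(k * 0.6)
      chrom <- c(rep(cl$chromosome[i], k1), rep("chrX", k - k1))
      start <- c(cl$base_position[i] + (seq_len(k1) - 1L) * cl$spacing_bp[i],
                 133.3e6 + (seq_len(k - k1) - 1L) * cl$spacing_bp[i])
      fam <- cl$name[i]
    } else {
      chrom <- rep(cl$chromosome[i], k)
      start <- cl$base_position[i] + (seq_len(k) - 1L) * cl$spacing_bp[i]
      fam <- NA_character_
    }
    data.frame(mirna_id = ids, chromosome = chrom, start = start,
               end = start + 80, strand = "+", family = fam,
               stringsAsFactors = FALSE)
  })
  validate_annotations(do.call(rbind, c(rows, list(bg))))
}

#' Write a simulated cohort to a directory
#'
#' Emits `ct.csv`, `annotations.gff3`, `families.tsv`, `metadata.csv` and
#' `truth.json` — the plain-text inputs the pipeline stages read.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ct_matrix(sim$ct, file.path(dir, "ct.csv"))
  write_annotations_gff3(sim$annotations, file.path(dir, "annotations.gff3"))
  fam <- sim$annotations[!is.na(sim$annotations$family),
                         c("mirna_id", "family")]
  utils::write.table(fam, file.path(dir, "families.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(sim$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  utils::write.table(sim$locus_labels, file.path(dir, "locus_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- sim$truth
  jsonlite::write_json(
    list(loadings = as.list(tr$loadings),
         mirna_cluster = as.list(tr$mirna_cluster),
         outcome_betas = as.list(tr$outcome_betas),
         gestational_age = as.list(tr$gestational_age),
         seed = tr$config$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
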