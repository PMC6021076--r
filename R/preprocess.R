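#' Hemolysis quality control for plasma miRNA panels
#'
#' Red blood cells are rich in miR-451a, while miR-23a-3p is stable in
#' plasma; a large CT gap `delta = CT(reference) - CT(red cell)` indicates
#' hemolysed plasma whose miRNA content no longer reflects circulation.
#' The conventional rule flags `delta > 7` cycles as hemolysed and logs
#' 5-7 as borderline. Samples are flagged, never dropped automatically.
#'
#' @param ct a [ct_matrix()].
#' @param red_cell_mirna,reference_mirna marker miRNA ids present in the
#'   matrix.
#' @param cutoff delta-CT (cycles) above which a sample is flagged.
#' @param borderline lower edge of the "borderline" band reported in the
#'   `note` column.
#' @return data.frame with one row per sample: `sample_id`,
#'   `hemolysis_delta` (cycles, NA when either marker failed to amplify),
#'   `hemolysis_flag` (`"ok"`, `"flagged"` or `"indeterminate"`), `note`,
#'   and `n_amplified` (count of amplified miRNAs in the sample).
#' @export
hemolysis_qc <- function(ct, red_cell_mirna = "hsa-miR-451a",
                         reference_mirna = "hsa-miR-23a-3p",
                         cutoff = 7, borderline = 5) {
  stopifnot(inherits(ct, "ct_matrix"))
  for (m in c(red_cell_mirna, reference_mirna))
    if (!m %in% ct$mirna_ids)
      stop("hemolysis marker '", m, "' not present in the CT matrix")
  rc <- ct$ct[, red_cell_mirna]
  ref <- ct$ct[, reference_mirna]
  delta <- ref - rc
  flag <- ifelse(is.na(delta), "indeterminate",
                 ifelse(delta > cutoff, "flagged", "ok"))
  note <- ifelse(!is.na(delta) & delta > borderline & delta <= cutoff,
                 "borderline", "")
  data.frame(sample_id = ct$sample_ids,
             hemolysis_delta = unname(delta),
             hemolysis_flag = unname(flag),
             note = unname(note),
             n_amplified = unname(rowSums(ct$amplified)),
             stringsAsFactors = FALSE)
}

#' Global-mean -dCT normalisation
#'
#' For each sample the mean CT over its *amplified* miRNAs is the global
#' reference; each amplified miRNA's -dCT is that mean minus its CT, so
#' higher -dCT means higher expression relative to the sample's global
#' level. Unamplified entries stay missing. A sample with fewer than two
#' amplified miRNAs has no meaningful global mean and is dropped with a
#' warning.
#'
#' By construction every retained sample's non-missing -dCT values average
#' to exactly zero, and adding a constant to all of one sample's CTs leaves
#' its -dCT unchanged.
#'
#' @param ct a [ct_matrix()].
#' @return an [expression_matrix()].
#' @export
normalize_global_mean <- function(ct) {
  stopifnot(inherits(ct, "ct_matrix"))
  n_amp <- rowSums(ct$amplified)
  drop <- n_amp < 2L
  if (any(drop)) {
    warning("dropping ", sum(drop), " sample(s) with < 2 amplified miRNAs: ",
            paste(ct$sample_ids[drop], collapse = ", "))
    if (all(drop)) stop("no sample has >= 2 amplified miRNAs")
  }
  m <- ct$ct[!drop, , drop = FALSE]
  gm <- rowMeans(m, na.rm = TRUE)
  dct <- sweep(-m, 1L, gm, FUN = "+")
  expression_matrix(dct)
}

#' Detection-prevalence filter
#'
#' Retains the miRNAs observed (amplified) in at least `min_samples`
#' samples — the panel inclusion rule of 30 of 42 samples by default.
#' Column order is preserved; the sample set is unchanged. The filter is
#' idempotent. For cohorts of other sizes use `min_fraction` instead
#' (`ceiling(min_fraction * n_samples)`, with 30/42 ~ 0.714).
#'
#' @param expr an [expression_matrix()].
#' @param min_samples minimum count of non-missing values per miRNA.
#' @param min_fraction alternative threshold as a fraction of samples;
#'   overrides `min_samples` when given.
#' @return the filtered [expression_matrix()].
#' @export
detection_filter <- function(expr, min_samples = 30, min_fraction = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  n <- nrow(expr$dct)
  if (!is.null(min_fraction)) min_samples <- ceiling(min_fraction * n)
  if (min_samples > n)
    stop("min_samples (", min_samples, ") exceeds the number of samples (",
         n, ")")
  keep <- colSums(!expr$missing) >= min_samples
  if (!any(keep))
    stop("detection filter at >= ", min_samples,
         " samples removes every miRNA")
  expression_matrix(expr$dct[, keep, drop = FALSE], check = FALSE)
}
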