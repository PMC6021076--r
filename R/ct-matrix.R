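#' Construct a cycle-threshold matrix
#'
#' A `ct_matrix` holds raw qPCR cycle thresholds (CT) for a panel of miRNAs
#' measured in a set of samples, together with an amplification mask. An
#' entry is *unamplified* when the instrument reported no CT, or when the
#' reported CT exceeds `unamplified_ct` (the panel software prints sentinel
#' CTs above the cycle limit for reactions that never crossed threshold).
#' Unamplified entries are treated as missing in every downstream statistic.
#'
#' @param ct numeric matrix, samples in rows, miRNAs in columns. `NA` cells
#'   are unamplified.
#' @param sample_ids,mirna_ids character vectors; default to dimnames of `ct`.
#' @param unamplified_ct cycle cutoff: CT strictly greater than this is
#'   marked unamplified. Default 50 (panel exports that run to 50 cycles);
#'   most instruments stop at 40, so set accordingly.
#' @return object of class `ct_matrix` with elements `ct` (numeric matrix,
#'   `NA` where unamplified), `amplified` (logical matrix) and
#'   `unamplified_ct`.
#' @examples
#' m <- matrix(c(28, 31, 52, 30, NA, 33), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("a", "b", "c")))
#' x <- ct_matrix(m)
#' x$amplified
#' @export
ct_matrix <- function(ct, sample_ids = rownames(ct), mirna_ids = colnames(ct),
                      unamplified_ct = 50) {
  if (!is.matrix(ct) || !is.numeric(ct))
    stop("`ct` must be a numeric matrix")
  if (is.null(sample_ids) || is.null(mirna_ids))
    stop("sample and miRNA identifiers are required (dimnames or arguments)")
  sample_ids <- as.character(sample_ids)
  mirna_ids <- as.character(mirna_ids)
  if (length(sample_ids) != nrow(ct) || length(mirna_ids) != ncol(ct))
    stop("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(mirna_ids))
    stop("duplicate miRNA ids: ",
         paste(unique(mirna_ids[duplicated(mirna_ids)]), collapse = ", "))
  dimnames(ct) <- list(sample_ids, mirna_ids)
  amplified <- is.finite(ct) & ct <= unamplified_ct
  ct[!amplified] <- NA_real_
  structure(
    list(ct = ct, amplified = amplified,
         sample_ids = sample_ids, mirna_ids = mirna_ids,
         unamplified_ct = unamplified_ct),
    class = "ct_matrix"
  )
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("ct_matrix: %d samples x %d miRNAs; %.1f%% amplified (CT <= %g)\n",
              nrow(x$ct), ncol(x$ct), 100 * mean(x$amplified),
              x$unamplified_ct))
  invisible(x)
}

#' @export
dim.ct_matrix <- function(x) dim(x$ct)

#' Read a CT matrix from a delimited text file
#'
#' Expects a rectangular table: header row of miRNA ids, first column sample
#' ids, remaining cells numeric CTs or empty (empty = unamplified). The
#' delimiter is sniffed from the extension (`.tsv`/`.txt` tab, otherwise
#' comma) unless given.
#'
#' @param path file path.
#' @param unamplified_ct CT cutoff; values strictly greater are unamplified.
#' @param sep field delimiter; `NULL` to infer from the extension.
#' @param transpose set `TRUE` for vendor exports with miRNAs in rows and
#'   samples in columns.
#' @return a [ct_matrix()].
#' @export
read_ct_matrix <- function(path, unamplified_ct = 50, sep = NULL,
                           transpose = FALSE) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("CT table needs a header and at least one row")
  # strsplit drops trailing empty fields; a sentinel keeps them
  cells <- lapply(strsplit(paste0(lines, sep, "\x01"), sep, fixed = TRUE),
                  function(x) x[-length(x)])
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop(sprintf("ragged CT table: row %d has %d fields, expected %d",
                 bad, widths[bad], widths[1L]))
  }
  header <- trimws(cells[[1L]])[-1L]
  body <- cells[-1L]
  row_ids <- vapply(body, function(r) trimws(r[1L]), character(1))
  vals <- lapply(body, function(r) {
    v <- trimws(r[-1L])
    v[v == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(v))
    if (any(!is.na(v) & is.na(num)))
      stop(sprintf("non-numeric CT value '%s' in row '%s'",
                   v[which(!is.na(v) & is.na(num))[1L]], trimws(r[1L])))
    num
  })
  m <- do.call(rbind, vals)
  dimnames(m) <- list(row_ids, header)
  if (transpose) m <- t(m)
  ct_matrix(m, unamplified_ct = unamplified_ct)
}

#' Write a CT matrix to a delimited text file
#'
#' Unamplified cells are written empty, so [read_ct_matrix()] round-trips
#' the amplification mask and the amplified values bit-identically.
#'
#' @param x a `ct_matrix`.
#' @param path output file; delimiter inferred from extension as in
#'   [read_ct_matrix()].
#' @export
write_ct_matrix <- function(x, path) {
  stopifnot(inherits(x, "ct_matrix"))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  m <- x$ct
  chr <- matrix(vapply(m, function(v)
    if (is.na(v)) "" else format(v, digits = 17), character(1)), nrow = nrow(m))
  out <- c(paste(c("sample_id", x$mirna_ids), collapse = sep),
           vapply(seq_len(nrow(m)), function(i)
             paste(c(x$sample_ids[i], chr[i, ]), collapse = sep), character(1)))
  writeLines(out, path)
  invisible(path)
}

#' Construct a normalised expression matrix
#'
#' Holds -dCT values: each amplified CT expressed relative to its sample's
#' global mean CT, negated so that larger values mean higher expression.
#' Produced by [normalize_global_mean()]; the constructor checks the
#' defining invariant that every sample's non-missing -dCT values average
#' to zero.
#'
#' @param dct numeric matrix of -dCT values with `NA` for missing entries.
#' @param sample_ids,mirna_ids identifiers; default to dimnames.
#' @param check enforce the per-sample zero-mean invariant (default TRUE;
#'   disable for externally normalised or subset matrices).
#' @return object of class `expression_matrix` with elements `dct`,
#'   `missing` (logical), `sample_ids`, `mirna_ids`.
#' @export
expression_matrix <- function(dct, sample_ids = rownames(dct),
                              mirna_ids = colnames(dct), check = TRUE) {
  if (!is.matrix(dct) || !is.numeric(dct))
    stop("`dct` must be a numeric matrix")
  sample_ids <- as.character(sample_ids)
  mirna_ids <- as.character(mirna_ids)
  if (anyDuplicated(sample_ids) || anyDuplicated(mirna_ids))
    stop("duplicate identifiers in expression matrix")
  dimnames(dct) <- list(sample_ids, mirna_ids)
  if (check) {
    mu <- rowMeans(dct, na.rm = TRUE)
    mu[!is.finite(mu)] <- 0
    if (any(abs(mu) > 1e-9))
      stop("per-sample mean of non-missing -dCT values must be 0 ",
           "(max |mean| = ", format(max(abs(mu))), "); use check = FALSE ",
           "for matrices not normalised by the global mean")
  }
  structure(
    list(dct = dct, missing = is.na(dct),
         sample_ids = sample_ids, mirna_ids = mirna_ids),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d samples x %d miRNAs; %.1f%% observed\n",
              nrow(x$dct), ncol(x$dct), 100 * mean(!x$missing)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$dct)

#' Write an expression matrix as CSV (empty cells for missing)
#' @param x an `expression_matrix`.
#' @param path output path.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(sample_id = x$sample_ids, x$dct, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
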