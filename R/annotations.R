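#' Construct a miRNA annotation table
#'
#' Genomic coordinates follow the GFF3 convention: 1-based, inclusive.
#' Strand is stored but not used by the cluster-chaining rule. `family` is
#' an optional named-family label (e.g. "miR-17/92") used to pool paralogous
#' loci across chromosomes.
#'
#' @param mirna_id,chromosome,start,end,strand,family vectors of equal
#'   length; `strand` defaults to `"*"`, `family` to `NA`.
#' @return data.frame of class `mirna_annotation`.
#' @export
mirna_annotation <- function(mirna_id, chromosome, start, end,
                             strand = "*", family = NA_character_) {
  df <- data.frame(mirna_id = as.character(mirna_id),
                   chromosome = as.character(chromosome),
                   start = as.numeric(start), end = as.numeric(end),
                   strand = rep_len(as.character(strand), length(mirna_id)),
                   family = rep_len(as.character(family), length(mirna_id)),
                   stringsAsFactors = FALSE)
  validate_annotations(df)
}

validate_annotations <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("mirna_id", "chromosome", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(nzchar(df$chromosome))) stop("empty chromosome name in annotations")
  if (any(!is.finite(df$start) | !is.finite(df$end)))
    stop("malformed genomic coordinate (non-finite start/end)")
  bad <- df$start > df$end
  if (any(bad))
    stop("start > end for: ", paste(df$mirna_id[bad], collapse = ", "))
  if (anyDuplicated(df$mirna_id))
    stop("duplicate annotation for: ",
         paste(unique(df$mirna_id[duplicated(df$mirna_id)]), collapse = ", "))
  if (!"strand" %in% names(df)) df$strand <- "*"
  if (!"family" %in% names(df)) df$family <- NA_character_
  class(df) <- c("mirna_annotation", "data.frame")
  df
}

#' Read miRNA annotations from a miRBase-style GFF3 file
#'
#' Keeps `miRNA` and `miRNA_primary_transcript` features and maps their
#' `Name` attribute to `mirna_id`. Features without a `Name` are skipped
#' with a warning. An optional two-column family table (mirna_id, family)
#' attaches named-family labels, used to pool paralogous clusters such as
#' miR-17/92 across chromosomes 13 and X.
#'
#' @param path GFF3 file.
#' @param family_table optional path to a two-column TSV, or a data.frame
#'   with columns `mirna_id` and `family`.
#' @param feature_types GFF3 feature types to keep.
#' @return a `mirna_annotation` data.frame.
#' @export
read_annotations <- function(path, family_table = NULL,
                             feature_types = c("miRNA",
                                               "miRNA_primary_transcript")) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    meta <- methods::slot(gr, "elementMetadata")
    keep <- as.character(meta$type) %in% feature_types
    gr <- gr[keep]
    meta <- methods::slot(gr, "elementMetadata")
    nm <- if ("Name" %in% colnames(meta)) as.character(meta$Name)
          else rep(NA_character_, length(gr))
    df <- data.frame(
      mirna_id = nm,
      chromosome = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE)
  } else {
    df <- parse_gff3_minimal(path, feature_types)
  }
  unnamed <- is.na(df$mirna_id) | !nzchar(df$mirna_id)
  if (any(unnamed)) {
    warning(sum(unnamed), " feature(s) without a Name attribute skipped")
    df <- df[!unnamed, , drop = FALSE]
  }
  df$family <- NA_character_
  if (!is.null(family_table)) {
    fam <- read_family_table(family_table)
    idx <- match(df$mirna_id, fam$mirna_id)
    df$family <- fam$family[idx]
  }
  rownames(df) <- NULL
  validate_annotations(df)
}

# fallback GFF3 parser (column 9 Name=... attribute), used only when
# rtracklayer is unavailable
parse_gff3_minimal <- function(path, feature_types) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) == 9L
  fields <- fields[ok]
  rows <- lapply(fields, function(f) {
    if (!f[3L] %in% feature_types) return(NULL)
    st <- suppressWarnings(as.numeric(f[4L]))
    en <- suppressWarnings(as.numeric(f[5L]))
    if (is.na(st) || is.na(en))
      stop("malformed coordinate in GFF3 record: ", paste(f, collapse = " "))
    attrs <- strsplit(f[9L], ";", fixed = TRUE)[[1L]]
    kv <- strsplit(attrs, "=", fixed = TRUE)
    nmv <- vapply(kv, function(x) if (length(x) == 2L) x[[1L]] else "",
                  character(1))
    name <- if (any(nmv == "Name"))
      kv[[which(nmv == "Name")[1L]]][[2L]] else NA_character_
    data.frame(mirna_id = name, chromosome = f[1L], start = st, end = en,
               strand = f[7L], stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows[!vapply(rows, is.null, logical(1))],
                   list(make.row.names = FALSE)))
}

read_family_table <- function(family_table) {
  if (is.character(family_table)) {
    fam <- utils::read.delim(family_table, header = TRUE,
                             stringsAsFactors = FALSE)
  } else fam <- as.data.frame(family_table)
  if (!all(c("mirna_id", "family") %in% names(fam)))
    stop("family table needs columns mirna_id, family")
  fam
}

#' Write annotations as GFF3
#'
#' Emits `miRNA_primary_transcript` records with a `Name` attribute,
#' readable by [read_annotations()] and by standard genome-browser tooling.
#'
#' @param ann a `mirna_annotation` data.frame.
#' @param path output file.
#' @export
write_annotations_gff3 <- function(ann, path) {
  ann <- validate_annotations(ann)
  strand <- ifelse(ann$strand %in% c("+", "-"), ann$strand, ".")
  rec <- sprintf("%s\t.\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                 ann$chromosome, as.integer(ann$start), as.integer(ann$end),
                 strand, ann$mirna_id, ann$mirna_id)
  writeLines(c("##gff-version 3", rec), path)
  invisible(path)
}

#' Read and validate a sample metadata table
#'
#' CSV with one row per sample. Required columns: `sample_id`, `group`
#' (term/PTB), `pair_id`. Outcome and covariate columns used downstream:
#' `gestational_age_birth` (weeks), `birth_weight` (g),
#' `head_circumference` (cm), `bmi` (kg/m^2), `gravida` (count),
#' `history_ptb` (0/1 or logical), `fetal_sex`.
#'
#' Validation: each `pair_id` occurs at most twice and, when twice, with one
#' term and one PTB member (error); the PTB label should agree with
#' gestational age <= `ptb_cutoff` weeks (warning only — the recorded label
#' is authoritative).
#'
#' @param path CSV file or a data.frame.
#' @param ptb_cutoff completed weeks defining preterm birth; default 37.
#' @return data.frame of class `sample_metadata`.
#' @export
read_metadata <- function(path, ptb_cutoff = 37) {
  md <- if (is.character(path))
    utils::read.csv(path, stringsAsFactors = FALSE) else as.data.frame(path)
  validate_metadata(md, ptb_cutoff = ptb_cutoff)
}

#' @rdname read_metadata
#' @param md a metadata data.frame.
#' @export
validate_metadata <- function(md, ptb_cutoff = 37) {
  need <- c("sample_id", "group", "pair_id")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata missing columns: ",
                         paste(miss, collapse = ", "))
  md$sample_id <- as.character(md$sample_id)
  if (anyDuplicated(md$sample_id)) stop("duplicate sample_id in metadata")
  if (!all(md$group %in% c("term", "PTB")))
    stop("group must be 'term' or 'PTB'; got: ",
         paste(setdiff(unique(md$group), c("term", "PTB")), collapse = ", "))
  tab <- table(md$pair_id)
  if (any(tab > 2L))
    stop("pair_id occurring more than twice: ",
         paste(names(tab)[tab > 2L], collapse = ", "))
  full <- names(tab)[tab == 2L]
  for (p in full) {
    g <- sort(md$group[md$pair_id == p])
    if (!identical(g, c("PTB", "term")))
      stop("pair ", p, " does not contain one term and one PTB member")
  }
  if ("gestational_age_birth" %in% names(md)) {
    implied <- ifelse(md$gestational_age_birth <= ptb_cutoff, "PTB", "term")
    off <- which(!is.na(md$gestational_age_birth) & implied != md$group)
    if (length(off))
      warning("group label disagrees with gestational age <= ", ptb_cutoff,
              " weeks for: ", paste(md$sample_id[off], collapse = ", "),
              " (label kept)")
  }
  if ("history_ptb" %in% names(md)) md$history_ptb <- as.integer(md$history_ptb)
  class(md) <- c("sample_metadata", "data.frame")
  md
}
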