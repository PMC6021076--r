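#' Assign miRNAs to genomic clusters by distance chaining
#'
#' Single-linkage chaining per chromosome: annotations are sorted by
#' (chromosome, start) and a new cluster starts whenever the gap between
#' the previous member's end and the next member's start exceeds `max_gap`
#' (overlapping intervals count as gap 0). The canonical rule groups
#' miRNAs lying within 10 kb of a neighbour on the same chromosome.
#' Chains of a single miRNA are reported as `unclustered` and excluded
#' from cluster-level statistics.
#'
#' miRNAs sharing a non-missing `family` label (e.g. the miR-17/92
#' paralogs on 13q31.3 and Xq26.2) are pooled into one named family
#' cluster regardless of chromosome; family membership takes precedence
#' over genomic chaining. Family members are ordered by (chromosome,
#' start).
#'
#' @param annotations a `mirna_annotation` data.frame
#'   (see [read_annotations()]).
#' @param max_gap maximum inter-interval gap in base pairs (default 10000).
#' @return object of class `cluster_map`: list with `clusters` (named list
#'   of ordered member id vectors), `membership` (named character vector
#'   mirna_id -> cluster name), `unclustered` (character vector), and
#'   `table` (per-miRNA data.frame with cluster, chromosome, start, end).
#' @export
assign_clusters <- function(annotations, max_gap = 10000) {
  ann <- validate_annotations(annotations)
  if (nrow(ann) == 0L) stop("no annotations supplied")

  is_fam <- !is.na(ann$family) & nzchar(ann$family)
  gen <- ann[!is_fam, , drop = FALSE]
  fam <- ann[is_fam, , drop = FALSE]

  clusters <- list()
  unclustered <- character(0)

  if (nrow(gen)) {
    gen <- gen[order(gen$chromosome, gen$start, gen$end, gen$mirna_id), ,
               drop = FALSE]
    new_chain <- c(TRUE, gen$chromosome[-1L] != gen$chromosome[-nrow(gen)])
    # gap from the running max end of the chain so far to the next start;
    # compute chain ids in one pass to honour single-linkage chaining
    chain <- integer(nrow(gen))
    cur <- 0L; cur_end <- -Inf; cur_chr <- ""
    for (i in seq_len(nrow(gen))) {
      gap <- gen$start[i] - cur_end  # distance prev.end -> next.start; <=0 overlap
      if (gen$chromosome[i] != cur_chr || gap > max_gap) {
        cur <- cur + 1L
        cur_chr <- gen$chromosome[i]
        cur_end <- gen$end[i]
      } else cur_end <- max(cur_end, gen$end[i])
      chain[i] <- cur
    }
    sizes <- table(chain)
    singleton <- as.integer(names(sizes)[sizes == 1L])
    unclustered <- gen$mirna_id[chain %in% singleton]
    k_per_chr <- integer(0)
    for (cid in setdiff(unique(chain), singleton)) {
      idx <- chain == cid
      chr <- gen$chromosome[idx][1L]
      k_per_chr[chr] <- (if (is.na(k_per_chr[chr])) 0L else k_per_chr[chr]) + 1L
      nm <- sprintf("%s_cluster%d", chr, k_per_chr[chr])
      clusters[[nm]] <- gen$mirna_id[idx]
    }
  }

  if (nrow(fam)) {
    fam <- fam[order(fam$chromosome, fam$start, fam$end, fam$mirna_id), ,
               drop = FALSE]
    for (f in unique(fam$family))
      clusters[[f]] <- fam$mirna_id[fam$family == f]
  }

  membership <- stats::setNames(
    rep(names(clusters), lengths(clusters)), unlist(clusters))
  tab_order <- c(unlist(clusters, use.names = FALSE), unclustered)
  idx <- match(tab_order, ann$mirna_id)
  tab <- data.frame(mirna_id = tab_order,
                    cluster = c(rep(names(clusters), lengths(clusters)),
                                rep(NA_character_, length(unclustered))),
                    chromosome = ann$chromosome[idx],
                    start = ann$start[idx], end = ann$end[idx],
                    stringsAsFactors = FALSE)
  structure(list(clusters = clusters, membership = membership,
                 unclustered = unclustered, table = tab,
                 max_gap = max_gap),
            class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  cat(sprintf("cluster_map: %d cluster(s), %d unclustered miRNA(s)\n",
              length(x$clusters), length(x$unclustered)))
  for (nm in names(x$clusters))
    cat(sprintf("  %-16s %d members\n", nm, length(x$clusters[[nm]])))
  invisible(x)
}

#' Rename genomic clusters by cytoband-style locus labels
#'
#' Clusters whose genomic footprint overlaps a labelled span take that
#' span's name — e.g. the chr14 cluster inside 14q32 becomes "c14mc" and
#' the chr19 cluster inside 19q13.41 becomes "c19mc". Spans come from a
#' user-supplied table so the package stays genome-build-agnostic. A
#' cluster overlapping two labelled spans is an error.
#'
#' @param map a `cluster_map`.
#' @param locus_labels data.frame with columns `chromosome`, `start`,
#'   `end`, `name`; `NULL` is the identity.
#' @return the renamed `cluster_map`.
#' @export
name_clusters <- function(map, locus_labels = NULL) {
  stopifnot(inherits(map, "cluster_map"))
  if (is.null(locus_labels) || !nrow(locus_labels)) return(map)
  need <- c("chromosome", "start", "end", "name")
  if (!all(need %in% names(locus_labels)))
    stop("locus_labels needs columns: ", paste(need, collapse = ", "))
  tab <- map$table
  new_names <- names(map$clusters)
  for (i in seq_along(map$clusters)) {
    members <- map$clusters[[i]]
    rows <- tab[match(members, tab$mirna_id), ]
    chr <- rows$chromosome[1L]
    lo <- min(rows$start); hi <- max(rows$end)
    hit <- which(locus_labels$chromosome == chr &
                   locus_labels$start <= hi & locus_labels$end >= lo)
    if (length(hit) > 1L)
      stop("cluster ", names(map$clusters)[i], " overlaps multiple labels: ",
           paste(locus_labels$name[hit], collapse = ", "))
    if (length(hit) == 1L) new_names[i] <- locus_labels$name[hit]
  }
  if (anyDuplicated(new_names))
    stop("locus labelling produced duplicate cluster names: ",
         paste(unique(new_names[duplicated(new_names)]), collapse = ", "))
  old <- names(map$clusters)
  names(map$clusters) <- new_names
  map$membership[] <- new_names[match(map$membership, old)]
  map$table$cluster <- ifelse(is.na(map$table$cluster), NA_character_,
                              new_names[match(map$table$cluster, old)])
  map
}

#' Serialise a cluster map
#'
#' Writes the per-miRNA assignment as TSV (`mirna_id`, `cluster`,
#' `chromosome`, `start`, `end`; unclustered miRNAs have an empty cluster
#' field) and, optionally, a JSON summary of cluster sizes and spans.
#'
#' @param map a `cluster_map`.
#' @param path output TSV path.
#' @param json_path optional JSON summary path.
#' @export
write_cluster_map <- function(map, path, json_path = NULL) {
  stopifnot(inherits(map, "cluster_map"))
  utils::write.table(map$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  if (!is.null(json_path)) {
    summ <- lapply(names(map$clusters), function(nm) {
      rows <- map$table[map$table$mirna_id %in% map$clusters[[nm]], ]
      list(name = nm, size = length(map$clusters[[nm]]),
           chromosomes = unique(rows$chromosome),
           span = c(min(rows$start), max(rows$end)))
    })
    jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a cluster map from its TSV serialisation
#' @param path TSV written by [write_cluster_map()].
#' @return a `cluster_map`.
#' @export
read_cluster_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  clustered <- tab[!is.na(tab$cluster), , drop = FALSE]
  clusters <- split(clustered$mirna_id, clustered$cluster)
  clusters <- clusters[unique(clustered$cluster)]  # keep file order
  membership <- stats::setNames(
    rep(names(clusters), lengths(clusters)), unlist(clusters))
  structure(list(clusters = clusters, membership = membership,
                 unclustered = tab$mirna_id[is.na(tab$cluster)],
                 table = tab, max_gap = NA_real_),
            class = "cluster_map")
}
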