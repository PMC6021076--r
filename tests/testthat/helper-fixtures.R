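# fixtures are built in code; nothing on disk

write_ct_file <- function(lines, ext = "csv") {
  path <- tempfile(fileext = paste0(".", ext))
  writeLines(lines, path)
  path
}

# toy 3-sample x 2-miRNA CT table with one empty cell
toy_ct_path <- function() {
  write_ct_file(c("sample_id,mirA,mirB",
                  "s1,30,31",
                  "s2,29,",
                  "s3,28,33"))
}

# annotation table builder
ann <- function(id, chr, start, end = start + 80, family = NA_character_) {
  mirna_annotation(id, chr, start, end, family = family)
}

# random annotation set on a handful of chromosomes, for oracle tests
random_annotations <- function(n, n_chr = 3, span = 1e5) {
  chr <- paste0("chr", sample.int(n_chr, n, replace = TRUE))
  start <- round(stats::runif(n, 1, span))
  mirna_annotation(sprintf("mir%03d", seq_len(n)), chr, start, start + 80)
}

# brute-force union-find oracle for the 10 kb chaining rule: two miRNAs
# share a cluster iff connected by a chain of pairwise interval gaps
# <= max_gap on one chromosome
oracle_clusters <- function(annotations, max_gap = 10000) {
  n <- nrow(annotations)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  gap <- function(i, j) {
    if (annotations$chromosome[i] != annotations$chromosome[j]) return(Inf)
    max(annotations$start[j] - annotations$end[i],
        annotations$start[i] - annotations$end[j], 0)
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && gap(i, j) <= max_gap) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(annotations$mirna_id, roots)
}

# partition of mirna ids implied by a cluster_map (clusters + singletons)
map_partition <- function(map) {
  parts <- c(unname(map$clusters),
             as.list(map$unclustered))
  canon <- lapply(parts, sort)
  canon[order(vapply(canon, `[`, character(1), 1L))]
}

oracle_partition <- function(oracle) {
  canon <- lapply(unname(oracle), sort)
  canon[order(vapply(canon, `[`, character(1), 1L))]
}

# small metadata table with paired design
toy_metadata <- function(n_pairs = 6, seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_pairs
    data.frame(
      sample_id = sprintf("s%02d", seq_len(n)),
      group = rep(c("term", "PTB"), each = n_pairs),
      pair_id = rep(sprintf("p%02d", seq_len(n_pairs)), 2),
      gestational_age_birth = c(pmax(37.1, rnorm(n_pairs, 38.6, 0.7)),
                                pmin(36.9, rnorm(n_pairs, 35.3, 1.5))),
      birth_weight = round(rnorm(n, 2850, 300)),
      head_circumference = round(rnorm(n, 32.6, 1.5), 1),
      bmi = round(rnorm(n, 25.7, 5), 1),
      gravida = sample(1:4, n, TRUE),
      history_ptb = rbinom(n, 1, 0.25),
      fetal_sex = sample(c("F", "M"), n, TRUE),
      stringsAsFactors = FALSE)
  })
}

# expression matrix straight from a dct matrix without the zero-mean check
expr_from <- function(m) expression_matrix(m, check = FALSE)
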