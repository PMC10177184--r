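# Independent brute-force oracles and tiny-fixture builders. These stay
# deliberately naive (per-base masks, exhaustive enumeration) so they
# cannot share a defect with the interval-algebra implementation.

# Per-base NGRE oracle: marks every base covered by a retroelement, then
# inspects each element and the frame base by base.
oracle_gene_ngre <- function(frame, elements, re, min_overlap = 1,
                             normalize = TRUE) {
  lim <- max(frame$end, elements$end, re$end, 1L)
  mask <- logical(lim)
  for (i in seq_len(nrow(re))) {
    if (re$chrom[i] == frame$chrom) {
      mask[(re$start[i] + 1L):re$end[i]] <- TRUE
    }
  }
  in_frame <- elements$chrom == frame$chrom &
    elements$end > frame$start & elements$start < frame$end
  el <- elements[in_frame, , drop = FALSE]
  n_total <- nrow(el)
  n_linked <- 0L
  for (i in seq_len(n_total)) {
    shared <- sum(mask[(el$start[i] + 1L):el$end[i]])
    if (shared >= min_overlap) n_linked <- n_linked + 1L
  }
  re_frac <- sum(mask[(frame$start + 1L):frame$end]) /
    (frame$end - frame$start)
  if (n_total == 0L) {
    ngre <- 0
  } else if (normalize) {
    ngre <- if (re_frac > 0) (n_linked / n_total) / re_frac else 0
  } else {
    ngre <- n_linked / n_total
  }
  list(n_total = n_total, n_re_linked = n_linked, re_fraction = re_frac,
       ngre = ngre)
}

# Random toy genome: a 10-kb frame with random peaks and retroelements,
# including intervals straddling the frame edges.
random_toy_frame <- function(max_elements = 100, max_re = 50) {
  off <- sample(0:5000, 1)
  frame <- data.frame(chrom = "chrT", start = off, end = off + 10000L)
  ne <- sample(0:max_elements, 1)
  es <- sample(max(0, off - 600):(off + 10500), ne, replace = TRUE)
  ew <- sample(50:500, max(ne, 1), replace = TRUE)[seq_len(ne)]
  nr <- sample(0:max_re, 1)
  rs <- sample(max(0, off - 2500):(off + 10500), nr, replace = TRUE)
  rw <- sample(50:2000, max(nr, 1), replace = TRUE)[seq_len(nr)]
  list(frame = frame,
       elements = data.frame(chrom = rep("chrT", ne), start = es,
                             end = es + ew, stringsAsFactors = FALSE),
       re = data.frame(chrom = rep("chrT", nr), start = rs, end = rs + rw,
                       stringsAsFactors = FALSE))
}

# Exhaustive hypergeometric upper tail: enumerate every n-subset of an
# N-element universe whose first K elements are "annotated" and count
# draws with at least k annotated members.
oracle_hyper_upper <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  cnt <- colSums(subsets <= K)
  mean(cnt >= k)
}

# Long-format NGRE table from a gene x profile score matrix.
long_from_matrix <- function(m, tags, cells) {
  stopifnot(ncol(m) == length(tags), length(tags) == length(cells))
  do.call(rbind, lapply(seq_len(ncol(m)), function(j) {
    data.frame(gene_id = rownames(m), tag = tags[j], cell_line = cells[j],
               n_total = 1L, n_re_linked = 0L, re_fraction = 0.1,
               ngre = m[, j], is_zero = m[, j] == 0,
               stringsAsFactors = FALSE)
  }))
}

# Full-vocabulary long table with one cell line per tag and identical
# per-gene values across tags unless a per-tag matrix is given.
full_tag_long <- function(values, n_cells = 1, tag_values = NULL) {
  tags <- tag_vocabulary()$all
  genes <- names(values)
  do.call(rbind, lapply(tags, function(tg) {
    do.call(rbind, lapply(seq_len(n_cells), function(cl) {
      v <- if (is.null(tag_values)) values else tag_values[, tg]
      data.frame(gene_id = genes, tag = tg, cell_line = paste0("CL", cl),
                 n_total = 1L, n_re_linked = 0L, re_fraction = 0.1,
                 ngre = unname(v), is_zero = unname(v) == 0,
                 stringsAsFactors = FALSE)
    }))
  }))
}

# Small synthetic configuration for module tests (kept light so the
# default suite stays fast).
tiny_config <- function(seed = 42, n_genes = 150L, ...) {
  synthetic_config(seed = seed, n_genes = n_genes, n_cell_lines_histone = 2L,
                   n_cell_lines_tfbs = 2L, n_planted = 10L,
                   pathway_size = 15L, n_pathways = 20L, n_terms = 15L,
                   term_size_range = c(5L, 30L), ...)
}
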