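# Collapse the gene x (tag, cell line) NGRE matrix into per-tag weighted
# averages, chromatin-class means and the aggregated NGRE_AGG per gene.
#
# Cell-line weights are a data-quality device: profiles with many zero
# scores (genes with no peaks, or no RE-linked peaks, in the frame) carry
# less information, so each (tag, cell line) profile is weighted by
# w = (1 - z)^3 where z is its zero fraction over the whole gene universe.

#' Proportion of zero scores in a profile
#' @param profile Numeric vector of scores for one (tag, cell line) profile
#'   over the full gene universe.
#' @return Fraction of exact zeros, in `[0, 1]`.
#' @export
#' @examples
#' zero_fraction(c(0, 1.2, 0, 3))
zero_fraction <- function(profile) {
  if (!length(profile)) stop("empty profile")
  mean(profile == 0)
}

#' Cell-line profile weight
#'
#' `w = (1 - z)^3`: a profile with no zeros has full weight 1, an all-zero
#' profile weight 0.
#'
#' @param z Zero fraction in `[0, 1]`.
#' @return Weight in `[0, 1]`.
#' @export
cell_line_weight <- function(z) {
  if (any(z < 0 | z > 1)) stop("z must lie in [0, 1]")
  (1 - z)^3
}

#' Weighted average of one gene's scores across cell lines
#'
#' Convex combination `sum(w * x) / sum(w)`. Zero scores are included:
#' they are real "no RE linkage" observations; the weights already
#' down-rank zero-heavy profiles.
#'
#' @param scores Numeric scores, one per cell line.
#' @param weights Matching weights.
#' @return The weighted mean, or `NA` (with a warning) when all weights
#'   are zero.
#' @export
weighted_tag_average <- function(scores, weights) {
  if (length(scores) != length(weights)) {
    stop("scores and weights must align")
  }
  sw <- sum(weights)
  if (sw == 0) {
    warning("all cell-line weights are zero; tag average undefined")
    return(NA_real_)
  }
  sum(weights * scores) / sw
}

#' Chromatin-class score means
#'
#' `NGRE_ac` is the unweighted mean of the four active-chromatin tags
#' (H3K9ac, H3K27ac, H3K4me3, H3K4me1); `NGRE_hc` the mean of the two
#' heterochromatin tags (H3K27me3, H3K9me3).
#'
#' @param tag_scores Named numeric vector of per-tag scores.
#' @return list with `ac` and `hc` (either `NA` if a required tag is
#'   missing).
#' @export
chromatin_class_scores <- function(tag_scores) {
  ac <- if (all(ACTIVE_TAGS %in% names(tag_scores)) &&
              !anyNA(tag_scores[ACTIVE_TAGS])) {
    mean(tag_scores[ACTIVE_TAGS])
  } else NA_real_
  hc <- if (all(HETEROCHROMATIN_TAGS %in% names(tag_scores)) &&
              !anyNA(tag_scores[HETEROCHROMATIN_TAGS])) {
    mean(tag_scores[HETEROCHROMATIN_TAGS])
  } else NA_real_
  list(ac = ac, hc = hc)
}

#' Aggregate the three class components into one score
#'
#' `NGRE_AGG = (NGRE_hc + NGRE_ac + NGRE_TFBS) / 3`; if any component is
#' missing the aggregate is missing (no silent renormalization).
#'
#' @param ac,hc,tfbs The three class components.
#' @return The equal-weight mean, or `NA`.
#' @export
aggregate_gene_score <- function(ac, hc, tfbs) {
  ifelse(is.na(ac) | is.na(hc) | is.na(tfbs), NA_real_, (hc + ac + tfbs) / 3)
}

# Shared engine: collapse a long (entity, tag, cell_line, value) table
# into per-tag weighted averages + class means + aggregate, given a
# weights table (tag, cell_line, z, w).
.aggregate_long <- function(long, weights, id_col, value_col) {
  ids <- unique(long[[id_col]])
  key <- paste0(long$tag, ":", long$cell_line)
  prof <- unique(data.frame(tag = long$tag, cell_line = long$cell_line,
                            key = key, stringsAsFactors = FALSE))
  m <- matrix(NA_real_, length(ids), nrow(prof),
              dimnames = list(ids, prof$key))
  m[cbind(match(long[[id_col]], ids), match(key, prof$key))] <- long[[value_col]]
  wkey <- paste0(weights$tag, ":", weights$cell_line)
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  names(out) <- id_col
  for (tg in ALL_TAGS) {
    cols <- prof$key[prof$tag == tg]
    col_out <- paste0("NGRE_", tg)
    if (!length(cols)) {
      out[[col_out]] <- NA_real_
      next
    }
    w <- weights$w[match(cols, wkey)]
    if (anyNA(w)) stop("missing weight for profile ", cols[is.na(w)][1L])
    if (sum(w) == 0) {
      warning("all cell-line weights are zero for tag ", tg)
      out[[col_out]] <- NA_real_
    } else {
      sub <- m[, cols, drop = FALSE]
      out[[col_out]] <- as.numeric(sub %*% w) / sum(w)
    }
  }
  out$NGRE_ac <- rowMeans(out[, paste0("NGRE_", ACTIVE_TAGS)])
  out$NGRE_hc <- rowMeans(out[, paste0("NGRE_", HETEROCHROMATIN_TAGS)])
  out$NGRE_AGG <- aggregate_gene_score(out$NGRE_ac, out$NGRE_hc,
                                       out$NGRE_TFBS)
  out
}

#' Compute cell-line weights from a raw NGRE matrix
#'
#' For each (tag, cell line) profile, the zero fraction `z` over the full
#' gene universe and the weight `w = (1 - z)^3`.
#'
#' @param ngre_long Long table from [compute_ngre_matrix()].
#' @return data.frame `tag`, `cell_line`, `z`, `w`.
#' @export
compute_cell_line_weights <- function(ngre_long) {
  prof <- unique(ngre_long[, c("tag", "cell_line")])
  key <- paste0(ngre_long$tag, ":", ngre_long$cell_line)
  z <- vapply(paste0(prof$tag, ":", prof$cell_line),
              function(k) zero_fraction(ngre_long$ngre[key == k]), 0)
  out <- data.frame(tag = prof$tag, cell_line = prof$cell_line,
                    z = unname(z), stringsAsFactors = FALSE)
  out$w <- cell_line_weight(out$z)
  out[order(match(out$tag, ALL_TAGS), out$cell_line), , drop = FALSE]
}

#' Aggregate the raw NGRE matrix into per-gene scores
#'
#' Computes zero-fraction weights per (tag, cell line), the weighted
#' per-tag averages, the chromatin-class means `NGRE_ac` / `NGRE_hc` and
#' the final `NGRE_AGG = (NGRE_hc + NGRE_ac + NGRE_TFBS) / 3`.
#'
#' @param ngre_long Long table from [compute_ngre_matrix()].
#' @return list with `scores` (wide data.frame, one row per gene, 10 NGRE
#'   columns) and `weights` (the [compute_cell_line_weights()] table).
#' @export
aggregate_ngre <- function(ngre_long) {
  weights <- compute_cell_line_weights(ngre_long)
  scores <- .aggregate_long(ngre_long, weights, "gene_id", "ngre")
  list(scores = scores, weights = weights)
}
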