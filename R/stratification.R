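# Four-group quantile stratification on the two evolutionary axes,
# hypergeometric over-representation with BH FDR, and the per-gene NGRE
# deviation (sign) test.

#' Empirical quantile threshold
#'
#' Linear interpolation between order statistics at position
#' `1 + q * (n - 1)` (the standard type-7 estimator).
#'
#' @param values Numeric vector; missing values dropped; at least 3
#'   non-missing values required.
#' @param q Quantile in (0, 1).
#' @return The threshold value.
#' @export
#' @examples
#' quantile_threshold(1:10, 0.8)  # 8.2
quantile_threshold <- function(values, q) {
  if (length(q) != 1L || q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  v <- values[!is.na(values)]
  if (length(v) < 3L) stop("need at least 3 non-missing values")
  unname(stats::quantile(v, q, type = 7))
}

#' Assign entities to the four evolutionary-regime groups
#'
#' "High" means strictly exceeding the upper-quantile threshold of a
#' metric, "low" strictly below the lower-quantile threshold; ties at a
#' threshold fall in neither tail. The four groups are the four
#' intersections of the regulatory and structural calls; everything else
#' (including entities missing either metric) is `unassigned`.
#'
#' @param entities data.frame whose first column identifies entities.
#' @param regulatory,structural Column names (or numeric vectors) of the
#'   two metrics.
#' @param q_low,q_high Quantile thresholds, defaults 0.2 and 0.8.
#' @return The input data.frame plus a `group` column with levels
#'   `high_high`, `high_reg_low_struct`, `low_reg_high_struct`,
#'   `low_low`, `unassigned`.
#' @export
assign_groups <- function(entities, regulatory = "NGRE_AGG",
                          structural = "dnds", q_low = 0.2, q_high = 0.8) {
  reg <- if (is.character(regulatory)) entities[[regulatory]] else regulatory
  str_ <- if (is.character(structural)) entities[[structural]] else structural
  stopifnot(length(reg) == nrow(entities), length(str_) == nrow(entities))
  grp <- rep("unassigned", nrow(entities))
  degenerate <- function(v) length(unique(v[!is.na(v)])) <= 1L
  if (degenerate(reg) || degenerate(str_)) {
    warning("a metric is constant; all entities unassigned")
  } else {
    reg_hi <- quantile_threshold(reg, q_high)
    reg_lo <- quantile_threshold(reg, q_low)
    str_hi <- quantile_threshold(str_, q_high)
    str_lo <- quantile_threshold(str_, q_low)
    ok <- !is.na(reg) & !is.na(str_)
    grp[ok & reg > reg_hi & str_ > str_hi] <- "high_high"
    grp[ok & reg > reg_hi & str_ < str_lo] <- "high_reg_low_struct"
    grp[ok & reg < reg_lo & str_ > str_hi] <- "low_reg_high_struct"
    grp[ok & reg < reg_lo & str_ < str_lo] <- "low_low"
  }
  entities$group <- factor(grp, levels = c("high_high", "high_reg_low_struct",
                                           "low_reg_high_struct", "low_low",
                                           "unassigned"))
  entities
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `p_adj(i) = min_{j >= rank(i)} (m * p_(j) / j)`,
#' capped at 1; input order preserved.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Hypergeometric over-representation analysis
#'
#' For each annotation term, the upper-tail hypergeometric probability of
#' drawing at least `k` annotated members in a group of size `n` from a
#' universe of size `N` containing `K` annotated genes, followed by BH
#' adjustment across the reported terms. Terms with no member in the
#' group are skipped by default (or reported with p = 1).
#'
#' @param group Character vector of entity ids; must be a subset of
#'   `universe`.
#' @param universe Character vector of all analyzed entity ids.
#' @param annotations Named list: term -> annotated ids (restricted to
#'   the universe internally).
#' @param report_zero Report terms with `k = 0` (p = 1)? Default FALSE.
#' @return data.frame `term_id`, `k`, `K`, `n`, `N`, `p`, `p_adj`, sorted
#'   by increasing p (ties by term id).
#' @export
hypergeometric_enrichment <- function(group, universe, annotations,
                                      report_zero = FALSE) {
  group <- unique(group)
  universe <- unique(universe)
  if (!all(group %in% universe)) stop("group must be a subset of the universe")
  N <- length(universe)
  n <- length(group)
  K <- vapply(annotations, function(a) sum(unique(a) %in% universe), 0L)
  k <- vapply(annotations, function(a) sum(unique(a) %in% group), 0L)
  keep <- if (report_zero) K > 0L else k > 0L
  term <- names(annotations)[keep]
  K <- K[keep]; k <- k[keep]
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term_id = term, k = unname(k), K = unname(K),
                    n = rep(n, length(term)), N = rep(N, length(term)),
                    p = unname(p), stringsAsFactors = FALSE,
                    row.names = NULL)
  out$p_adj <- bh_adjust(out$p)
  out[order(out$p, out$term_id), , drop = FALSE]
}

#' Drop terms shared by every group
#'
#' Optional post-filter on a list of enrichment tables (one per group):
#' removes terms significant (`p_adj < alpha`) in all groups, which carry
#' no group-discriminating information.
#'
#' @param enrichments Named list of [hypergeometric_enrichment()] tables.
#' @param alpha Significance level, default 0.05.
#' @return The list with shared significant terms removed.
#' @export
filter_shared_terms <- function(enrichments, alpha = 0.05) {
  sig <- lapply(enrichments, function(e) e$term_id[e$p_adj < alpha])
  shared <- Reduce(intersect, sig)
  lapply(enrichments, function(e) e[!(e$term_id %in% shared), , drop = FALSE])
}

#' Per-gene NGRE deviation test
#'
#' Exact one-sided sign tests of each gene's per-profile scores against
#' the global mean score, in both directions; values equal to the mean
#' are dropped. Genes with fewer than `min_values` usable values are
#' skipped (their count is reported in a message). Each direction is BH
#' adjusted across genes separately; `p_adj_below < 0.05` selects genes
#' whose scores sit consistently below the global average.
#'
#' @param profile_matrix Numeric matrix, genes x profiles (e.g. the
#'   per-cell-line scores of one tag, or all profiles); rownames are gene
#'   ids.
#' @param global_mean Reference level; default the mean over the whole
#'   matrix.
#' @param min_values Minimum usable values per gene, default 5.
#' @return data.frame `gene_id`, `n_used`, `n_below`, `n_above`,
#'   `p_below`, `p_above`, `p_adj_below`, `p_adj_above`.
#' @export
gene_deviation_test <- function(profile_matrix,
                                global_mean = mean(profile_matrix, na.rm = TRUE),
                                min_values = 5L) {
  stopifnot(is.matrix(profile_matrix))
  x <- profile_matrix
  below <- rowSums(x < global_mean, na.rm = TRUE)
  above <- rowSums(x > global_mean, na.rm = TRUE)
  used <- below + above
  keep <- used >= min_values
  if (any(!keep)) {
    message("[deviation] ", sum(!keep), " genes skipped (fewer than ",
            min_values, " usable values)")
  }
  below <- below[keep]; above <- above[keep]; used <- used[keep]
  p_below <- stats::pbinom(below - 1L, used, 0.5, lower.tail = FALSE)
  p_above <- stats::pbinom(above - 1L, used, 0.5, lower.tail = FALSE)
  ids <- rownames(x)[keep]
  if (is.null(ids)) ids <- as.character(which(keep))
  data.frame(gene_id = ids, n_used = as.integer(used),
             n_below = as.integer(below), n_above = as.integer(above),
             p_below = unname(p_below), p_above = unname(p_above),
             p_adj_below = bh_adjust(unname(p_below)),
             p_adj_above = bh_adjust(unname(p_above)),
             stringsAsFactors = FALSE, row.names = NULL)
}
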