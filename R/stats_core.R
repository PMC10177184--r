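# Spearman correlation with large-sample p-values, all-pairs correlation
# matrices over the evolutionary metrics, and Ward.D2 leaf ordering for
# reporting.

#' Spearman rank correlation with p-value
#'
#' rho is the Pearson correlation of mid-ranks (average ranks for ties);
#' the p-value uses the large-sample t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' Pairs with a missing side are dropped.
#'
#' @param x,y Paired numeric vectors.
#' @return list `rho`, `p`, `n`; `rho` is `NA` (and `p` `NA`) when either
#'   side has zero rank variance.
#' @export
spearman <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5L) stop("need at least 5 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("zero rank variance; correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rx, ry)
  if (abs(rho) == 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' All-pairs Spearman correlation matrix with Ward.D2 ordering
#'
#' Pairwise complete-case Spearman correlation for every pair of metric
#' columns, with a matching p-value matrix, and a reporting order from
#' Ward.D2 agglomerative clustering on the distance `1 - rho`.
#'
#' @param table data.frame or matrix, entities x metrics (numeric
#'   columns). Metrics with no non-missing values are excluded with a
#'   message.
#' @return Object of class `correlation_matrix`: list with `rho`, `p`
#'   (symmetric matrices, unit diagonal), `order` (integer permutation)
#'   and `labels`.
#' @export
correlation_matrix <- function(table) {
  m <- as.matrix(as.data.frame(table))
  storage.mode(m) <- "double"
  if (ncol(m) < 2L) stop("need at least 2 metrics")
  empty <- colSums(!is.na(m)) == 0L
  if (any(empty)) {
    message("[correlate] excluding all-missing metrics: ",
            paste(colnames(m)[empty], collapse = ", "))
    m <- m[, !empty, drop = FALSE]
  }
  k <- ncol(m)
  rho <- diag(1, k)
  p <- matrix(0, k, k)
  dimnames(rho) <- dimnames(p) <- list(colnames(m), colnames(m))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      s <- spearman(m[, i], m[, j])
      rho[i, j] <- rho[j, i] <- s$rho
      p[i, j] <- p[j, i] <- s$p
    }
  }
  d <- 1 - rho
  d[is.na(d)] <- 1
  ord <- stats::hclust(stats::as.dist(d), method = "ward.D2")$order
  structure(list(rho = rho, p = p, order = ord, labels = colnames(m)),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 3, ...) {
  cat("Spearman correlation matrix (", length(x$labels), " metrics, ",
      "Ward.D2 order)\n", sep = "")
  print(round(x$rho[x$order, x$order], digits))
  invisible(x)
}

#' Write a correlation matrix as three TSV files
#'
#' `<prefix>_rho.tsv`, `<prefix>_p.tsv` (matrices with a `metric` id
#' column) and `<prefix>_order.tsv` (the Ward.D2 leaf order).
#'
#' @param cm A [correlation_matrix()] object.
#' @param prefix Path prefix.
#' @return Invisibly, the three paths.
#' @export
write_correlation_matrix <- function(cm, prefix) {
  paths <- paste0(prefix, c("_rho.tsv", "_p.tsv", "_order.tsv"))
  write_score_table(data.frame(metric = cm$labels, cm$rho,
                               check.names = FALSE), paths[1L])
  write_score_table(data.frame(metric = cm$labels, cm$p,
                               check.names = FALSE), paths[2L])
  write_score_table(data.frame(position = seq_along(cm$order),
                               metric = cm$labels[cm$order]), paths[3L])
  invisible(paths)
}
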