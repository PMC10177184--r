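# Pathway-level metrics: mean member dN/dS (structural axis), normalized
# pathway involvement index NPII (regulatory axis, per profile, then
# aggregated like the gene level), and node-level means for pathway charts.

#' Mean dN/dS of a pathway's members
#'
#' Unweighted mean over member genes that carry a dN/dS value; members
#' without a value are excluded and counted.
#'
#' @param members Character vector of member gene symbols.
#' @param dnds Named numeric vector (gene -> dN/dS, `NA` allowed).
#' @return list `dnds_pw`, `n_genes_matched`, `n_excluded`; `dnds_pw` is
#'   `NA` when no member has a value (pathway unscorable).
#' @export
pathway_dnds <- function(members, dnds) {
  members <- unique(members)
  v <- dnds[match(members, names(dnds))]
  ok <- !is.na(v)
  list(dnds_pw = if (any(ok)) mean(v[ok]) else NA_real_,
       n_genes_matched = sum(ok), n_excluded = length(members) - sum(ok))
}

#' Normalized pathway involvement index for one profile
#'
#' NPII = (mean score of matched members) / (mean score over the whole
#' gene universe of the profile). 1.0 is the neutral value: a pathway
#' spanning all genes scores exactly 1. Set `normalize = FALSE` for the
#' plain member mean.
#'
#' @param members Character vector of member gene symbols.
#' @param profile Named numeric vector: score per gene for one
#'   (tag, cell line) profile; defines the background universe.
#' @param normalize Divide by the background mean? Default TRUE.
#' @return NPII value, or `NA` when no member matches the universe.
#' @export
pathway_npii <- function(members, profile, normalize = TRUE) {
  members <- unique(members)
  v <- profile[match(members, names(profile))]
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  if (!normalize) return(mean(v))
  bg <- mean(profile, na.rm = TRUE)
  if (!is.finite(bg) || bg == 0) stop("background mean is zero; NPII undefined")
  mean(v) / bg
}

#' Per-profile NPII matrix for a pathway collection
#'
#' @param pathways Named list of member-symbol vectors ([read_gmt()]).
#' @param ngre_long Raw long table from [compute_ngre_matrix()].
#' @param normalize See [pathway_npii()].
#' @return Long data.frame `pathway_id`, `tag`, `cell_line`, `npii`,
#'   `n_genes_matched`. Pathways with no matched member in a profile get
#'   `NA` there.
#' @export
compute_npii_matrix <- function(pathways, ngre_long, normalize = TRUE) {
  prof <- unique(ngre_long[, c("tag", "cell_line")])
  key <- paste0(ngre_long$tag, ":", ngre_long$cell_line)
  pkey <- paste0(prof$tag, ":", prof$cell_line)
  ids <- unique(ngre_long$gene_id)
  m <- matrix(NA_real_, length(ids), nrow(prof),
              dimnames = list(ids, pkey))
  m[cbind(match(ngre_long$gene_id, ids), match(key, pkey))] <- ngre_long$ngre
  bg <- colMeans(m, na.rm = TRUE)
  if (normalize && any(!is.finite(bg) | bg == 0)) {
    stop("background mean is zero for profile ",
         pkey[which(!is.finite(bg) | bg == 0)[1L]])
  }
  idx <- lapply(pathways, function(mem) {
    i <- match(unique(mem), ids)
    i[!is.na(i)]
  })
  out <- vector("list", length(pathways))
  for (p in seq_along(pathways)) {
    i <- idx[[p]]
    if (length(i)) {
      mm <- colMeans(m[i, , drop = FALSE], na.rm = TRUE)
      nmatch <- colSums(!is.na(m[i, , drop = FALSE]))
      npii <- if (normalize) mm / bg else mm
      npii[nmatch == 0L] <- NA_real_
    } else {
      npii <- rep(NA_real_, nrow(prof))
      nmatch <- rep(0L, nrow(prof))
    }
    out[[p]] <- data.frame(pathway_id = names(pathways)[p],
                           tag = prof$tag, cell_line = prof$cell_line,
                           npii = unname(npii),
                           n_genes_matched = as.integer(nmatch),
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Aggregate per-profile NPII values into pathway scores
#'
#' Reuses the gene-level machinery: cell-line weights `(1 - z)^3` with `z`
#' taken from the gene-level profiles, class means for active chromatin
#' and heterochromatin, then `NPII_AGG = (NPII_hc + NPII_ac + NPII_TFBS)/3`.
#'
#' @param npii_long Output of [compute_npii_matrix()].
#' @param weights Gene-level weights table
#'   ([compute_cell_line_weights()]).
#' @return Wide data.frame, one row per pathway, columns `NPII_<tag>`,
#'   `NPII_ac`, `NPII_hc`, `NPII_TFBS`, `NPII_AGG`.
#' @export
aggregate_pathway_scores <- function(npii_long, weights) {
  out <- .aggregate_long(npii_long, weights, "pathway_id", "npii")
  names(out) <- sub("^NGRE_", "NPII_", names(out))
  out
}

#' Full pathway score table
#'
#' Combines the aggregated NPII columns with the member-mean dN/dS.
#' Pathways with no member carrying a dN/dS value are reported with
#' `dnds_pw = NA` (and excluded downstream, with a message giving the
#' count of unscorable pathways).
#'
#' @param pathways Named list of member vectors.
#' @param ngre_long Raw NGRE long table.
#' @param dnds Named dN/dS vector.
#' @param weights Gene-level weights table.
#' @param normalize See [pathway_npii()].
#' @return data.frame with `pathway_id`, `n_genes_matched` (dN/dS
#'   matches), `dnds_pw` and the NPII columns.
#' @export
compute_pathway_scores <- function(pathways, ngre_long, dnds, weights,
                                   normalize = TRUE) {
  npii <- compute_npii_matrix(pathways, ngre_long, normalize)
  agg <- aggregate_pathway_scores(npii, weights)
  dd <- lapply(pathways, pathway_dnds, dnds = dnds)
  dtab <- data.frame(pathway_id = names(pathways),
                     n_genes_matched = vapply(dd, `[[`, 0, "n_genes_matched"),
                     dnds_pw = vapply(dd, `[[`, 0, "dnds_pw"),
                     stringsAsFactors = FALSE, row.names = NULL)
  out <- merge(dtab, agg, by = "pathway_id", sort = TRUE)
  n_bad <- sum(is.na(out$dnds_pw) | is.na(out$NPII_AGG))
  if (n_bad) {
    message("[pathways] ", n_bad, " of ", nrow(out),
            " pathways lack one of the two axes and are unscorable")
  }
  out
}

#' Node-level scores for pathway charts
#'
#' Per (pathway, node): the unweighted mean dN/dS and mean NGRE_AGG over
#' member genes carrying each metric. A missing flag is set per metric
#' when no member carries it (charts draw such nodes with a distinct
#' shape/color).
#'
#' @param topology list from [read_topology()] (`nodes`, `edges`).
#' @param dnds Named dN/dS vector.
#' @param gene_scores Wide gene score table ([aggregate_ngre()]`$scores`).
#' @return data.frame `pathway_id`, `node_id`, `n_genes`, `node_dnds`,
#'   `node_ngre_agg`, `dnds_missing`, `ngre_missing`.
#' @export
node_scores <- function(topology, dnds, gene_scores) {
  nodes <- topology$nodes
  if (!nrow(nodes)) stop("topology has no nodes")
  ngre <- stats::setNames(gene_scores$NGRE_AGG, gene_scores$gene_id)
  keyf <- interaction(nodes$pathway_id, nodes$node_id, drop = TRUE,
                      lex.order = TRUE)
  sp <- split(nodes$gene, keyf)
  meta <- nodes[!duplicated(keyf), c("pathway_id", "node_id")]
  meta <- meta[order(meta$pathway_id, meta$node_id), , drop = FALSE]
  stat <- function(genes, values) {
    v <- values[match(genes, names(values))]
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }
  if (any(lengths(sp) == 0L)) stop("node with no member genes")
  nd <- vapply(sp, stat, 0, values = dnds)
  ng <- vapply(sp, stat, 0, values = ngre)
  data.frame(pathway_id = meta$pathway_id, node_id = meta$node_id,
             n_genes = as.integer(lengths(sp)), node_dnds = unname(nd),
             node_ngre_agg = unname(ng), dnds_missing = unname(is.na(nd)),
             ngre_missing = unname(is.na(ng)), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Export a node-attributed pathway chart
#'
#' Writes `nodes.tsv` (node_id, node_dnds, node_ngre_agg, dnds_missing,
#' ngre_missing; sorted by node_id) and `edges.tsv` (source, target,
#' label) for one pathway, loadable as a directed node-attributed graph
#' (e.g. for Cytoscape-style rendering: node color from NGRE_AGG, node
#' size from mean dN/dS). Re-export is byte-identical.
#'
#' @param nodes One pathway's rows from [node_scores()].
#' @param edges data.frame `source`, `target`, `label`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
export_pathway_chart <- function(nodes, edges, dir) {
  bad <- !(edges$source %in% nodes$node_id & edges$target %in% nodes$node_id)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("edge references unknown node: ", edges$source[i], " -> ",
         edges$target[i])
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nodes <- nodes[order(nodes$node_id),
                 c("node_id", "node_dnds", "node_ngre_agg",
                   "dnds_missing", "ngre_missing")]
  edges <- edges[order(edges$source, edges$target, edges$label),
                 c("source", "target", "label")]
  np <- file.path(dir, "nodes.tsv")
  ep <- file.path(dir, "edges.tsv")
  write_score_table(nodes, np)
  write_score_table(edges, ep)
  invisible(c(nodes = np, edges = ep))
}
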