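# One-shot orchestration: score -> aggregate -> pathways -> stratify ->
# enrich -> correlate, with stage-tagged logging to stderr, plain-TSV
# outputs and a JSON manifest recording config, input checksums and the
# counts at every filtering step. Rerunning with the same config yields
# checksum-identical outputs.

.log <- function(stage, ..., verbose = TRUE) {
  if (verbose) message("[", stage, "] ", ...)
}

#' Read a pipeline run configuration
#'
#' YAML with keys `genes`, `re_bed`, `tracks` (a TSV index with columns
#' tag, cell_line, path, or an inline list), optional `dnds`, `gmt`,
#' `nodes`, `edges`, `terms`, and the parameters `frame_size` (default
#' 10000), `min_overlap` (1), `normalize` (TRUE), `q_low` (0.2), `q_high`
#' (0.8), `fdr` (0.05), `seed` (1). Relative paths resolve against the
#' YAML file's directory.
#'
#' @param path Path to the YAML file.
#' @return Config list with absolute input paths and defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  absol <- function(p) {
    if (is.null(p)) NULL
    else ifelse(grepl("^/", p), p, file.path(base, p))
  }
  for (key in c("genes", "re_bed", "tracks", "dnds", "gmt", "nodes",
                "edges", "terms")) {
    cfg[[key]] <- absol(cfg[[key]])
  }
  defaults <- list(frame_size = 10000L, min_overlap = 1L, normalize = TRUE,
                   q_low = 0.2, q_high = 0.8, fdr = 0.05, seed = 1L)
  for (key in names(defaults)) {
    if (is.null(cfg[[key]])) cfg[[key]] <- defaults[[key]]
  }
  cfg
}

.load_tracks <- function(path) {
  idx <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("tag", "cell_line", "path") %in% names(idx)))
  base <- dirname(normalizePath(path))
  lapply(seq_len(nrow(idx)), function(i) {
    p <- idx$path[i]
    if (!grepl("^/", p)) p <- file.path(base, p)
    regulatory_track(idx$tag[i], idx$cell_line[i], read_bed(p))
  })
}

#' Run the full evolutionary-rate pipeline
#'
#' Executes every stage against the configured inputs and writes
#' `ngre_raw.tsv`, `weights.tsv`, `ngre_agg.tsv`, `merged.tsv`,
#' `deviation_genes.tsv`, and when pathway/annotation inputs are present
#' `pathway_scores.tsv`, `groups_genes.tsv`, `groups_pathways.tsv`,
#' `enrichment_<group>.tsv`, `corr_genes_{rho,p,order}.tsv`, per-pathway
#' chart exports under `charts/`, plus `manifest.json` (config, input
#' MD5 checksums, package version, and the counts logged at each
#' filtering step). Any stage error aborts the run with the stage name.
#'
#' @param config A config list ([read_run_config()]) or the path to a
#'   run YAML.
#' @param outdir Output directory.
#' @param verbose Log stage progress to stderr? Default TRUE.
#' @return Invisibly, `outdir`.
#' @export
run_pipeline <- function(config, outdir, verbose = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  counts <- list()
  pth <- function(f) file.path(outdir, f)

  .log("score", "reading inputs", verbose = verbose)
  genes <- read_gene_annotation(config$genes)
  re <- read_bed(config$re_bed)
  tracks <- .load_tracks(config$tracks)
  counts$genes_total <- nrow(genes)
  counts$tracks <- length(tracks)
  .log("score", "scoring ", nrow(genes), " genes x ", length(tracks),
       " tracks", verbose = verbose)
  ngre <- compute_ngre_matrix(genes, tracks, re,
                              frame_size = config$frame_size,
                              min_overlap = config$min_overlap,
                              normalize = config$normalize)
  write_score_table(ngre, pth("ngre_raw.tsv"))

  .log("aggregate", "computing cell-line weights and NGRE_AGG",
       verbose = verbose)
  agg <- aggregate_ngre(ngre)
  write_score_table(agg$weights, pth("weights.tsv"))
  write_score_table(agg$scores, pth("ngre_agg.tsv"))

  .log("deviation", "sign tests against the global mean", verbose = verbose)
  key <- paste0(ngre$tag, ":", ngre$cell_line)
  ids <- unique(ngre$gene_id)
  profs <- unique(key)
  pm <- matrix(NA_real_, length(ids), length(profs),
               dimnames = list(ids, profs))
  pm[cbind(match(ngre$gene_id, ids), match(key, profs))] <- ngre$ngre
  dev <- gene_deviation_test(pm)
  write_score_table(dev, pth("deviation_genes.tsv"))
  counts$genes_below_average <- sum(dev$p_adj_below < config$fdr)

  merged <- agg$scores
  if (!is.null(config$dnds)) {
    dnds <- read_dnds(config$dnds)
    merged$dnds <- unname(dnds[match(merged$gene_id, names(dnds))])
    counts$genes_matched_dnds <- sum(!is.na(merged$dnds))
    .log("merge", counts$genes_matched_dnds, " of ", nrow(merged),
         " genes carry dN/dS", verbose = verbose)
  }
  write_score_table(merged, pth("merged.tsv"))

  if (!is.null(config$dnds)) {
    .log("correlate", "gene-level metric correlation matrix",
         verbose = verbose)
    metrics <- merged[, setdiff(names(merged), "gene_id")]
    cm <- correlation_matrix(metrics)
    write_correlation_matrix(cm, pth("corr_genes"))

    .log("stratify", "gene four-group assignment", verbose = verbose)
    gg <- assign_groups(merged[, c("gene_id", "NGRE_AGG", "dnds")],
                        "NGRE_AGG", "dnds",
                        q_low = config$q_low, q_high = config$q_high)
    write_score_table(gg, pth("groups_genes.tsv"))
    counts$gene_group_sizes <- as.list(table(gg$group)[
      c("high_high", "high_reg_low_struct", "low_reg_high_struct", "low_low")])
    .log("stratify", "gene groups: ",
         paste(names(counts$gene_group_sizes),
               unlist(counts$gene_group_sizes), sep = "=", collapse = ", "),
         verbose = verbose)

    if (!is.null(config$terms)) {
      .log("enrich", "hypergeometric ORA per gene group", verbose = verbose)
      terms <- read_term_annotations(config$terms)
      universe <- gg$gene_id[!is.na(gg$NGRE_AGG) & !is.na(gg$dnds)]
      for (grp in c("high_high", "high_reg_low_struct",
                    "low_reg_high_struct", "low_low")) {
        members <- gg$gene_id[gg$group == grp]
        if (length(members) == 0L) next
        enr <- hypergeometric_enrichment(members, universe, terms)
        write_score_table(enr, pth(paste0("enrichment_", grp, ".tsv")))
      }
    }
  }

  if (!is.null(config$gmt) && !is.null(config$dnds)) {
    .log("pathways", "pathway dN/dS and NPII", verbose = verbose)
    pathways <- read_gmt(config$gmt)
    counts$pathways_total <- length(pathways)
    ps <- compute_pathway_scores(pathways, ngre, dnds, agg$weights,
                                 normalize = config$normalize)
    write_score_table(ps, pth("pathway_scores.tsv"))
    scored <- !is.na(ps$dnds_pw) & !is.na(ps$NPII_AGG)
    counts$pathways_scored <- sum(scored)
    .log("pathways", counts$pathways_scored, " of ", length(pathways),
         " pathways scorable on both axes", verbose = verbose)

    .log("stratify", "pathway four-group assignment", verbose = verbose)
    pg <- assign_groups(ps[scored, c("pathway_id", "NPII_AGG", "dnds_pw")],
                        "NPII_AGG", "dnds_pw",
                        q_low = config$q_low, q_high = config$q_high)
    write_score_table(pg, pth("groups_pathways.tsv"))
    counts$pathway_group_sizes <- as.list(table(pg$group)[
      c("high_high", "high_reg_low_struct", "low_reg_high_struct", "low_low")])

    if (!is.null(config$nodes) && !is.null(config$edges)) {
      .log("charts", "node scores and chart export", verbose = verbose)
      topo <- read_topology(config$nodes, config$edges)
      ns <- node_scores(topo, dnds, agg$scores)
      write_score_table(ns, pth("node_scores.tsv"))
      for (pw in unique(ns$pathway_id)) {
        export_pathway_chart(ns[ns$pathway_id == pw, , drop = FALSE],
                             topo$edges[topo$edges$pathway_id == pw,
                                        c("source", "target", "label"),
                                        drop = FALSE],
                             file.path(outdir, "charts", pw))
      }
    }
  }

  .log("manifest", "writing manifest.json", verbose = verbose)
  inputs <- Filter(Negate(is.null),
                   config[c("genes", "re_bed", "tracks", "dnds", "gmt",
                            "nodes", "edges", "terms")])
  checksums <- lapply(inputs, function(p) unname(tools::md5sum(p)))
  manifest <- list(
    tool = "retrospect",
    version = as.character(utils::packageVersion("retrospect")),
    config = config[c("frame_size", "min_overlap", "normalize", "q_low",
                      "q_high", "fdr", "seed")],
    inputs = checksums,
    counts = counts)
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(outdir)
}
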