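# Synthetic input generator. Emulates every pipeline input with controlled
# statistical structure: a one-chromosome genome with evenly spaced TSSs
# (disjoint 10-kb frames), retroelement intervals hitting a target genome
# coverage, per-(tag, cell line) peak tracks with planted per-gene
# RE-linkage driven by a latent variable u, zero-inflated frames, dN/dS
# coupled to the same latent, coherently sampled pathway gene sets with
# node topologies, and term annotations including one planted term.
#
# A single latent u_g per gene drives both axes: each peak in gene g's
# frame is RE-linked with probability plogis(theta_base + theta_slope*u_g),
# and log dN/dS mixes u with independent noise at weight rho_latent.
# Pathway membership is sampled coherently on a noisy copy of u
# (pathway_coherence), emulating the functional coherence of real pathway
# collections; this is what makes pathway-level correlations exceed the
# gene-level one, as observed on the real data the generator emulates.

#' Build a synthetic-data configuration
#'
#' Defaults mirror the study conditions the pipeline is designed for:
#' a 10-kb scoring frame, 6 histone tags x 5 cell lines plus TFBS x 13
#' cell lines, and desk-scale gene/pathway counts (5,000 genes, 500
#' pathways of 50 genes). `rho_latent` is calibrated so the gene-level
#' Spearman correlation between NGRE_AGG and dN/dS is ~0.10, and
#' `pathway_coherence` so the pathway-level correlation is ~0.4.
#'
#' @param seed Integer seed; fully determines all outputs.
#' @param n_genes Number of genes.
#' @param gene_spacing Distance between consecutive TSSs (bases).
#' @param frame_size Scoring frame width (bases).
#' @param chrom Chromosome name.
#' @param n_cell_lines_histone,n_cell_lines_tfbs Cell lines per histone
#'   tag / for TFBS.
#' @param re_coverage Target genome-wide RE base-coverage fraction.
#' @param frame_re_count Retroelements placed inside every frame (each
#'   frame is guaranteed RE content, as gene-proximal regions are in the
#'   human genome).
#' @param frame_re_width,re_width Width ranges (bases) for frame-internal
#'   and intergenic retroelements (SINE-to-LINE scale).
#' @param peak_width Regulatory-element (peak) width in bases.
#' @param peak_rate Mean peak count per non-empty frame.
#' @param zero_rate Probability a (gene, tag, cell line) frame has no
#'   peaks.
#' @param theta_base,theta_slope RE-linkage logit model: a peak in gene
#'   g's frame overlaps an RE with probability
#'   `plogis(theta_base + theta_slope * u_g)`.
#' @param n_planted,planted_shift Number of planted fast-regulatory genes
#'   and the shift added to their latent u.
#' @param rho_latent Weight of the shared latent in log dN/dS, in [0, 1].
#' @param dnds_log_mean,dnds_log_sd Location/scale of log dN/dS.
#' @param dnds_missing_rate Fraction of genes without a dN/dS value.
#' @param pathway_coherence Weight of u in the latent ordering used to
#'   sample pathway members, in [0, 1]; 0 gives fully random pathways.
#' @param pathway_size,n_pathways Pathway geometry.
#' @param n_terms,term_size_range Random annotation terms.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_genes = 5000L,
                             gene_spacing = 20000L, frame_size = 10000L,
                             chrom = "chr1",
                             n_cell_lines_histone = 5L,
                             n_cell_lines_tfbs = 13L,
                             re_coverage = 0.25, frame_re_count = 2L,
                             frame_re_width = c(600L, 1000L),
                             re_width = c(150L, 6000L), peak_width = 200L,
                             peak_rate = 7, zero_rate = 0.2,
                             theta_base = -1, theta_slope = 2,
                             n_planted = 100L, planted_shift = 3,
                             rho_latent = 0.1, dnds_log_mean = log(0.25),
                             dnds_log_sd = 0.5, dnds_missing_rate = 0.05,
                             pathway_coherence = 0.75, pathway_size = 50L,
                             n_pathways = 500L, n_terms = 200L,
                             term_size_range = c(20L, 200L)) {
  cfg <- as.list(environment())
  probs <- c(re_coverage = re_coverage, zero_rate = zero_rate,
             rho_latent = rho_latent, pathway_coherence = pathway_coherence,
             dnds_missing_rate = dnds_missing_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  }
  if (gene_spacing < frame_size) {
    stop("gene_spacing must be >= frame_size so frames are disjoint")
  }
  if (pathway_size > n_genes) stop("pathway_size exceeds n_genes")
  structure(cfg, class = "synthetic_config")
}

.cell_line_names <- function(kind, n) {
  pool <- if (kind == "histone") {
    c("GM12878", "HeLa-S3", "HepG2", "K562", "MCF-7")
  } else {
    c("GM12878", "GM12891", "HeLa-S3", "HepG2", "K562", "HEK293", "HEK293T",
      "A549", "SK-N-SH", "HCT116", "Ishikawa", "MCF-10A", "MCF-7")
  }
  if (n <= length(pool)) pool[seq_len(n)] else c(pool, sprintf("CL%02d", seq_len(n - length(pool))))
}

#' Generate gene annotation, retroelement track and regulatory tracks
#'
#' TSSs are spaced `gene_spacing` apart so all frames are disjoint. Every
#' frame receives `frame_re_count` retroelements; intergenic gaps are then
#' filled with retroelements until the genome-wide union coverage is
#' within 0.01 of `re_coverage`. Peaks are placed per (gene, tag, cell
#' line): a frame is empty with probability `zero_rate`, otherwise it
#' holds `1 + Poisson(peak_rate - 1)` peaks, each overlapping a frame
#' retroelement with probability `plogis(theta_base + theta_slope * u_g)`
#' and placed RE-free otherwise.
#'
#' @param config A [synthetic_config()].
#' @return list: `genes` (annotation data.frame), `re` (interval
#'   data.frame), `tracks` (list of [regulatory_track()]), `latent`
#'   (named u vector), `planted` (planted gene ids).
#' @export
make_regulatory_inputs <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_genes
  sp <- config$gene_spacing
  fs <- config$frame_size
  L <- n * sp
  if (n * fs > L) stop("frames would overlap: n_genes * frame_size > chrom_length")
  tss <- as.integer(sp / 2 + (0:(n - 1)) * sp)
  gene_id <- sprintf("G%05d", seq_len(n))
  genes <- data.frame(gene_id = gene_id, symbol = gene_id,
                      chrom = config$chrom, tss = tss,
                      strand = rep(c("+", "-"), length.out = n),
                      stringsAsFactors = FALSE)
  u <- stats::rnorm(n)
  planted <- sort(sample.int(n, config$n_planted))
  u[planted] <- u[planted] + config$planted_shift
  names(u) <- gene_id

  fstart <- tss - fs %/% 2L
  fend <- tss + fs %/% 2L

  # Frame retroelements: frame_re_count per frame, guaranteed inside.
  k <- config$frame_re_count
  fw <- matrix(as.integer(stats::runif(n * k, config$frame_re_width[1L],
                                       config$frame_re_width[2L] + 1)),
               n, k)
  fs_ <- matrix(0L, n, k)
  for (j in seq_len(k)) {
    fs_[, j] <- fstart + as.integer(stats::runif(n) * (fs - fw[, j]))
  }
  fe_ <- fs_ + fw
  frame_re <- data.frame(chrom = config$chrom, start = as.vector(t(fs_)),
                         end = as.vector(t(fe_)), stringsAsFactors = FALSE)

  # Intergenic fill to the genome-wide coverage target.
  gaps_start <- c(0L, fend[-n], fend[n])
  gaps_end <- c(fstart, L)
  gap_len <- gaps_end - gaps_start
  keep <- gap_len > config$re_width[1L]
  gaps_start <- gaps_start[keep]; gaps_end <- gaps_end[keep]
  gap_len <- gaps_end - gaps_start
  target <- config$re_coverage * L
  cover <- function(df) {
    sum(IRanges::width(IRanges::reduce(.iranges(df$start, df$end))))
  }
  covered <- cover(frame_re)
  fill <- list()
  mean_w <- mean(config$re_width)
  it <- 0L
  while (covered < target - 0.01 * L) {
    it <- it + 1L
    if (it > 200L) stop("cannot reach re_coverage target ", config$re_coverage)
    nb <- max(1L, as.integer(0.7 * (target - covered) / mean_w))
    gi <- sample.int(length(gap_len), nb, replace = TRUE, prob = gap_len)
    wmax <- pmin(config$re_width[2L], gap_len[gi])
    w <- as.integer(stats::runif(nb, config$re_width[1L], wmax + 1))
    s <- gaps_start[gi] + as.integer(stats::runif(nb) * (gap_len[gi] - w))
    fill[[it]] <- data.frame(chrom = config$chrom, start = s, end = s + w,
                             stringsAsFactors = FALSE)
    covered <- cover(rbind(frame_re, do.call(rbind, fill)))
  }
  re <- rbind(frame_re, do.call(rbind, fill))
  re <- re[order(re$start, re$end), , drop = FALSE]
  rownames(re) <- NULL
  re$name <- sprintf("RE%06d", seq_len(nrow(re)))

  # Peak tracks.
  p_link <- stats::plogis(config$theta_base + config$theta_slope * u)
  pw <- config$peak_width
  tags <- rep(c(HISTONE_TAGS, "TFBS"),
              times = c(rep(config$n_cell_lines_histone, length(HISTONE_TAGS)),
                        config$n_cell_lines_tfbs))
  cells <- c(unlist(lapply(HISTONE_TAGS, function(t) {
    .cell_line_names("histone", config$n_cell_lines_histone)
  })), .cell_line_names("tfbs", config$n_cell_lines_tfbs))
  tracks <- vector("list", length(tags))
  for (ti in seq_along(tags)) {
    empty <- stats::runif(n) < config$zero_rate
    npk <- ifelse(empty, 0L, 1L + stats::rpois(n, config$peak_rate - 1))
    gidx <- rep.int(seq_len(n), npk)
    m <- length(gidx)
    linked <- stats::runif(m) < p_link[gidx]
    start <- integer(m)
    if (any(linked)) {
      li <- which(linked)
      j <- 1L + as.integer(stats::runif(length(li)) * k)
      rs <- fs_[cbind(gidx[li], j)]
      re_ <- fe_[cbind(gidx[li], j)]
      lo <- pmax(fstart[gidx[li]], rs - pw + 1L)
      hi <- pmin(re_ - 1L, fend[gidx[li]] - pw)
      bad <- hi < lo
      hi[bad] <- lo[bad] <- pmax(fstart[gidx[li]][bad],
                                 pmin(rs[bad], fend[gidx[li]][bad] - pw))
      start[li] <- lo + as.integer(stats::runif(length(li)) * (hi - lo + 1L))
    }
    ni <- which(!linked)
    if (length(ni)) {
      s <- fstart[gidx[ni]] + as.integer(stats::runif(length(ni)) * (fs - pw))
      for (iter in seq_len(30L)) {
        ov <- rep(FALSE, length(ni))
        for (j in seq_len(k)) {
          a <- fs_[gidx[ni], j]; b <- fe_[gidx[ni], j]
          ov <- ov | (s < b & s + pw > a)
        }
        if (!any(ov)) break
        redo <- which(ov)
        s[redo] <- fstart[gidx[ni][redo]] +
          as.integer(stats::runif(length(redo)) * (fs - pw))
      }
      start[ni] <- s
    }
    el <- data.frame(chrom = config$chrom, start = start, end = start + pw,
                     stringsAsFactors = FALSE)
    tracks[[ti]] <- regulatory_track(tags[ti], cells[ti], el)
  }
  list(genes = genes, re = re, tracks = tracks, latent = u,
       planted = gene_id[planted])
}

#' Generate dN/dS values coupled to the regulatory latent
#'
#' `dnds_g = exp(mu + sd * (rho * u_g + sqrt(1 - rho^2) * e_g))` with
#' `e_g` standard normal: values are strictly positive and the rank
#' correlation with any monotone function of `u` is tuned by
#' `rho_latent`. A `dnds_missing_rate` fraction of genes gets `NA`.
#'
#' @param config A [synthetic_config()].
#' @param latent Named latent vector from [make_regulatory_inputs()].
#' @return Named numeric vector (gene -> dN/dS).
#' @export
make_dnds <- function(config, latent) {
  set.seed(config$seed + 1L)
  rho <- config$rho_latent
  e <- stats::rnorm(length(latent))
  v <- exp(config$dnds_log_mean +
             config$dnds_log_sd * (rho * latent + sqrt(1 - rho^2) * e))
  if (config$dnds_missing_rate > 0) {
    v[stats::runif(length(v)) < config$dnds_missing_rate] <- NA_real_
  }
  stats::setNames(as.numeric(v), names(latent))
}

#' Generate pathways, topologies and term annotations
#'
#' Pathway members are consecutive runs of genes ordered by a noisy copy
#' of the latent (`s = coherence * u + sqrt(1 - coherence^2) * w`),
#' started at random positions: pathways are distinct but may overlap,
#' and genes within a pathway share evolutionary regime to the degree set
#' by `pathway_coherence`. Each pathway is partitioned into 3-8 nonempty
#' nodes joined by a random connected directed edge set. Terms are random
#' gene sets; when `planted` is supplied, one extra term annotates
#' exactly the planted genes.
#'
#' @param config A [synthetic_config()].
#' @param gene_ids Character vector of gene identifiers.
#' @param latent Named latent vector.
#' @param planted Optional planted gene ids for the planted term.
#' @return list: `pathways` (named member list, GMT-ready), `topology`
#'   (list of `nodes`/`edges` data.frames), `terms` (named list).
#' @export
make_pathways_and_terms <- function(config, gene_ids, latent,
                                    planted = NULL) {
  set.seed(config$seed + 2L)
  n <- length(gene_ids)
  m <- config$pathway_size
  P <- config$n_pathways
  coh <- config$pathway_coherence
  s <- coh * latent + sqrt(1 - coh^2) * stats::rnorm(n)
  ord <- order(s)
  # Pathway windows are stratified over the latent ordering (a curated
  # collection spans the functional spectrum) with random jitter.
  grid <- seq(1, n - m + 1L, length.out = P)
  jit <- stats::runif(P, -(n - m) / (2 * P), (n - m) / (2 * P))
  starts <- pmin(pmax(as.integer(round(grid + jit)), 1L), n - m + 1L)
  starts <- sample(starts)
  ids <- sprintf("PW%04d", seq_len(P))
  pathways <- lapply(starts, function(st) gene_ids[ord[st:(st + m - 1L)]])
  names(pathways) <- ids
  attr(pathways, "description") <- stats::setNames(
    rep("synthetic pathway", P), ids)

  nodes <- vector("list", P)
  edges <- vector("list", P)
  for (p in seq_len(P)) {
    k <- sample(3:8, 1L)
    assign <- sample(rep(seq_len(k), length.out = m))
    nodes[[p]] <- data.frame(pathway_id = ids[p],
                             node_id = sprintf("N%02d", assign),
                             gene = pathways[[p]], stringsAsFactors = FALSE)
    from <- vapply(2:k, function(i) sample.int(i - 1L, 1L), 0L)
    ef <- c(from, sample.int(k, k %/% 2L, replace = TRUE))
    et <- c(2:k, sample.int(k, k %/% 2L, replace = TRUE))
    keep <- ef != et
    edges[[p]] <- unique(data.frame(
      pathway_id = ids[p], source = sprintf("N%02d", ef[keep]),
      target = sprintf("N%02d", et[keep]),
      label = sample(c("activation", "inhibition"), sum(keep),
                     replace = TRUE),
      stringsAsFactors = FALSE))
  }
  topology <- list(nodes = do.call(rbind, nodes),
                   edges = do.call(rbind, edges))

  sizes <- as.integer(stats::runif(config$n_terms, config$term_size_range[1L],
                                   config$term_size_range[2L] + 1))
  terms <- lapply(sizes, function(sz) sample(gene_ids, sz))
  names(terms) <- sprintf("T%04d", seq_len(config$n_terms))
  if (!is.null(planted)) terms$PLANTED_SET <- planted
  list(pathways = pathways, topology = topology, terms = terms)
}

#' Generate the complete synthetic input bundle
#'
#' Runs [make_regulatory_inputs()], [make_dnds()] and
#' [make_pathways_and_terms()] under one configuration.
#'
#' @param config A [synthetic_config()].
#' @return list of class `retrospect_sim` with elements `config`, `genes`,
#'   `re`, `tracks`, `dnds`, `pathways`, `topology`, `terms`, `latent`,
#'   `planted`.
#' @export
simulate_inputs <- function(config = synthetic_config()) {
  reg <- make_regulatory_inputs(config)
  dnds <- make_dnds(config, reg$latent)
  pt <- make_pathways_and_terms(config, reg$genes$gene_id, reg$latent,
                                planted = reg$planted)
  structure(c(list(config = config), reg,
              list(dnds = dnds, pathways = pt$pathways,
                   topology = pt$topology, terms = pt$terms)),
            class = "retrospect_sim")
}

#' @export
print.retrospect_sim <- function(x, ...) {
  cat(sprintf(paste0("<retrospect_sim: %d genes, %d RE intervals, %d tracks, ",
                     "%d pathways, %d terms, seed %d>\n"),
              nrow(x$genes), nrow(x$re), length(x$tracks),
              length(x$pathways), length(x$terms), x$config$seed))
  invisible(x)
}

#' Write a synthetic bundle to pipeline input files
#'
#' Emits `genes.tsv`, `re.bed`, one `<tag>_<cell_line>.bed` per track plus
#' a `tracks.tsv` index, `dnds.tsv`, `pathways.gmt`, `nodes.tsv`,
#' `edges.tsv`, `terms.tsv`, and a ready-to-run `run.yaml` pipeline
#' configuration.
#'
#' @param sim A [simulate_inputs()] bundle.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the path to `run.yaml`.
#' @export
write_synthetic_inputs <- function(sim, dir) {
  stopifnot(inherits(sim, "retrospect_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(dir, f)
  write_score_table(sim$genes, pth("genes.tsv"))
  write_bed(sim$re, pth("re.bed"))
  tr <- data.frame(tag = vapply(sim$tracks, `[[`, "", "tag"),
                   cell_line = vapply(sim$tracks, `[[`, "", "cell_line"),
                   stringsAsFactors = FALSE)
  tr$path <- paste0(tr$tag, "_", tr$cell_line, ".bed")
  for (i in seq_along(sim$tracks)) {
    write_bed(sim$tracks[[i]]$elements, pth(tr$path[i]))
  }
  write_score_table(tr, pth("tracks.tsv"))
  write_score_table(data.frame(gene_id = names(sim$dnds),
                               dnds = unname(sim$dnds)), pth("dnds.tsv"))
  write_gmt(sim$pathways, pth("pathways.gmt"))
  write_score_table(sim$topology$nodes, pth("nodes.tsv"))
  write_score_table(sim$topology$edges, pth("edges.tsv"))
  ann <- data.frame(term_id = rep(names(sim$terms), lengths(sim$terms)),
                    gene_id = unlist(sim$terms, use.names = FALSE),
                    stringsAsFactors = FALSE)
  write_score_table(ann, pth("terms.tsv"))
  cfg <- list(genes = "genes.tsv", re_bed = "re.bed", tracks = "tracks.tsv",
              dnds = "dnds.tsv", gmt = "pathways.gmt", nodes = "nodes.tsv",
              edges = "edges.tsv", terms = "terms.tsv",
              frame_size = sim$config$frame_size, min_overlap = 1L,
              normalize = TRUE, q_low = 0.2, q_high = 0.8, fdr = 0.05,
              seed = sim$config$seed)
  yaml::write_yaml(cfg, pth("run.yaml"))
  invisible(pth("run.yaml"))
}
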