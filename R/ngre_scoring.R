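# Raw NGRE scoring: RE-linked fraction of regulatory elements in the 10-kb
# TSS frame, normalized by the RE base-coverage of the frame. Interval
# arithmetic is 0-based half-open externally; IRanges (1-based closed) is
# used internally, converted as [start+1, end].

.iranges <- function(start0, end0) {
  IRanges::IRanges(start = start0 + 1L, end = end0)
}

#' Construct a regulatory track
#'
#' Bundles a set of ChIP-seq peak intervals with its functional tag and
#' cell line. TFBS tracks are expected to pool all transcription factors
#' of a cell line into one element set.
#'
#' @param tag One of `tag_vocabulary()$all`.
#' @param cell_line Cell line name.
#' @param elements data.frame of intervals (`chrom`, `start`, `end`).
#' @return An object of class `regulatory_track`.
#' @export
regulatory_track <- function(tag, cell_line, elements) {
  if (!tag %in% ALL_TAGS) {
    stop("unknown functional tag '", tag, "'; expected one of: ",
         paste(ALL_TAGS, collapse = ", "))
  }
  stopifnot(all(c("chrom", "start", "end") %in% names(elements)))
  if (nrow(elements) && any(elements$start < 0 | elements$start >= elements$end)) {
    stop("invalid intervals in track ", tag, ":", cell_line)
  }
  structure(list(tag = tag, cell_line = cell_line,
                 elements = elements[, c("chrom", "start", "end")]),
            class = "regulatory_track")
}

#' @export
print.regulatory_track <- function(x, ...) {
  cat(sprintf("<regulatory_track %s:%s, %d elements>\n",
              x$tag, x$cell_line, nrow(x$elements)))
  invisible(x)
}

#' Build the scoring frame around a TSS
#'
#' The frame is `frame_size` bases centered on the TSS,
#' `[max(0, tss - frame_size/2), tss + frame_size/2)`, clipped at the
#' chromosome origin. Strand is ignored: the frame is symmetric.
#'
#' @param gene One-row data.frame (or list) with `chrom` and `tss`.
#' @param frame_size Frame width in bases; even, positive. Default 10000.
#' @return One-row data.frame `chrom`, `start`, `end`.
#' @export
#' @examples
#' build_tss_frame(list(chrom = "chr1", tss = 100000))
build_tss_frame <- function(gene, frame_size = 10000) {
  if (length(frame_size) != 1L || frame_size <= 0 || frame_size %% 2 != 0) {
    stop("frame_size must be a positive even number of bases")
  }
  half <- frame_size / 2
  data.frame(chrom = gene$chrom,
             start = as.integer(pmax(0, gene$tss - half)),
             end = as.integer(gene$tss + half),
             stringsAsFactors = FALSE)
}

# Per-element overlap width against the union of RE intervals (same chrom
# assumed); returns integer vector aligned with `elements`.
.re_overlap_widths <- function(elements, re) {
  widths <- integer(nrow(elements))
  if (!nrow(elements) || !nrow(re)) return(widths)
  for (ch in unique(elements$chrom)) {
    qi <- which(elements$chrom == ch)
    si <- re$chrom == ch
    if (!any(si)) next
    q <- .iranges(elements$start[qi], elements$end[qi])
    s <- IRanges::reduce(.iranges(re$start[si], re$end[si]))
    hits <- IRanges::findOverlaps(q, s)
    if (length(hits)) {
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      w <- pmin(IRanges::end(q)[qh], IRanges::end(s)[sh]) -
        pmax(IRanges::start(q)[qh], IRanges::start(s)[sh]) + 1L
      agg <- rowsum(w, qh)
      widths[qi[as.integer(rownames(agg))]] <- as.integer(agg)
    }
  }
  widths
}

#' Classify regulatory elements as RE-linked
#'
#' An element is RE-linked when it shares at least `min_overlap` bases with
#' the union of retroelement intervals; it is counted once no matter how
#' many retroelements it touches.
#'
#' @param elements data.frame of intervals (`chrom`, `start`, `end`).
#' @param re_track data.frame of retroelement intervals.
#' @param min_overlap Minimum shared bases (>= 1). Default 1.
#' @return list with `n_total` and `n_re_linked`.
#' @export
classify_re_linked <- function(elements, re_track, min_overlap = 1) {
  if (min_overlap < 1) stop("min_overlap must be >= 1")
  ov <- .re_overlap_widths(elements, re_track)
  list(n_total = nrow(elements), n_re_linked = sum(ov >= min_overlap))
}

#' RE base-coverage fraction of a frame
#'
#' Overlapping retroelements are merged before measuring; the result is
#' (bases of the frame covered by the RE union) / frame length.
#'
#' @param frame One-row data.frame `chrom`, `start`, `end`.
#' @param re_track data.frame of retroelement intervals.
#' @return Fraction in `[0, 1]`.
#' @export
re_coverage_fraction <- function(frame, re_track) {
  len <- frame$end - frame$start
  stopifnot(len > 0)
  ov <- .re_overlap_widths(frame, re_track)
  ov / len
}

#' Compute the NGRE score for one gene and one track
#'
#' Counts the track's peaks overlapping the gene's TSS frame (any overlap
#' puts a peak in the frame; peaks are not merged -- each peak is one
#' regulatory element), classifies them against the retroelement union,
#' and scores
#' `ngre = (n_re_linked / n_total) / re_fraction` when both `n_total > 0`
#' and `re_fraction > 0`. Genes with an empty frame score 0 with
#' `is_zero = TRUE`; a frame without RE content also scores 0 (no RE
#' content means no RE linkage). With `normalize = FALSE` the score is the
#' plain RE-linked fraction.
#'
#' @param gene One-row data.frame/list with `gene_id`, `chrom`, `tss`.
#' @param track A [regulatory_track()].
#' @param re_track data.frame of retroelement intervals.
#' @param frame_size,min_overlap See [build_tss_frame()],
#'   [classify_re_linked()].
#' @param normalize Divide by the frame's RE coverage fraction? Default TRUE.
#' @return One-row data.frame: `gene_id`, `tag`, `cell_line`, `n_total`,
#'   `n_re_linked`, `re_fraction`, `ngre`, `is_zero`.
#' @export
compute_gene_ngre <- function(gene, track, re_track, frame_size = 10000,
                              min_overlap = 1, normalize = TRUE) {
  frame <- build_tss_frame(gene, frame_size)
  el <- track$elements
  if (!frame$chrom %in% el$chrom && !frame$chrom %in% re_track$chrom) {
    warning("chromosome ", frame$chrom, " absent from tracks; gene ",
            gene$gene_id, " scored as zero frame")
  }
  el <- el[el$chrom == frame$chrom &
             el$end > frame$start & el$start < frame$end, , drop = FALSE]
  cls <- classify_re_linked(el, re_track, min_overlap)
  re_frac <- re_coverage_fraction(frame, re_track)
  n_total <- cls$n_total
  n_linked <- cls$n_re_linked
  if (n_total == 0L) {
    ngre <- 0
  } else if (normalize) {
    ngre <- if (re_frac > 0) (n_linked / n_total) / re_frac else 0
  } else {
    ngre <- n_linked / n_total
  }
  data.frame(gene_id = gene$gene_id, tag = track$tag,
             cell_line = track$cell_line, n_total = n_total,
             n_re_linked = n_linked, re_fraction = re_frac, ngre = ngre,
             is_zero = n_total == 0L, stringsAsFactors = FALSE)
}

# Vectorized scoring of all genes against one track; same semantics as
# compute_gene_ngre (kept as an independent per-gene reference path and
# tested for equality).
.score_track <- function(genes, frames, track, re_track, min_overlap,
                         normalize, re_frac) {
  n <- nrow(genes)
  n_total <- integer(n)
  n_linked <- integer(n)
  el <- track$elements
  for (ch in unique(frames$chrom)) {
    gi <- which(frames$chrom == ch)
    ei <- which(el$chrom == ch)
    if (!length(ei)) next
    q <- .iranges(frames$start[gi], frames$end[gi])
    e <- .iranges(el$start[ei], el$end[ei])
    linked <- .re_overlap_widths(el[ei, , drop = FALSE],
                                 re_track[re_track$chrom == ch, , drop = FALSE]) >= min_overlap
    hits <- IRanges::findOverlaps(q, e)
    if (length(hits)) {
      qh <- S4Vectors::queryHits(hits)
      tot <- tabulate(qh, nbins = length(gi))
      lnk <- tabulate(qh[linked[S4Vectors::subjectHits(hits)]],
                      nbins = length(gi))
      n_total[gi] <- tot
      n_linked[gi] <- lnk
    }
  }
  ngre <- numeric(n)
  nz <- n_total > 0L
  if (normalize) {
    ok <- nz & re_frac > 0
    ngre[ok] <- (n_linked[ok] / n_total[ok]) / re_frac[ok]
  } else {
    ngre[nz] <- n_linked[nz] / n_total[nz]
  }
  data.frame(gene_id = genes$gene_id, tag = track$tag,
             cell_line = track$cell_line, n_total = n_total,
             n_re_linked = n_linked, re_fraction = re_frac, ngre = ngre,
             is_zero = !nz, stringsAsFactors = FALSE)
}

#' Compute the full gene x (tag, cell line) NGRE matrix
#'
#' Scores every gene against every track; every cell is filled (zero-frame
#' genes included) and the result is deterministic and invariant to track
#' input order (rows are ordered by track tag/cell line as given, genes in
#' annotation order).
#'
#' @param genes Gene annotation data.frame ([read_gene_annotation()]).
#' @param tracks List of [regulatory_track()] objects; duplicate
#'   (tag, cell line) pairs are rejected.
#' @param re_track data.frame of retroelement intervals.
#' @inheritParams compute_gene_ngre
#' @return Long-format data.frame, one row per (gene, tag, cell line).
#' @export
compute_ngre_matrix <- function(genes, tracks, re_track, frame_size = 10000,
                                min_overlap = 1, normalize = TRUE) {
  if (!length(tracks)) stop("at least one regulatory track is required")
  keys <- vapply(tracks, function(t) paste0(t$tag, ":", t$cell_line), "")
  if (anyDuplicated(keys)) {
    stop("duplicate (tag, cell line) track: ", keys[duplicated(keys)][1L])
  }
  frames <- build_tss_frame(genes, frame_size)
  re_frac <- numeric(nrow(genes))
  for (ch in unique(frames$chrom)) {
    gi <- which(frames$chrom == ch)
    ov <- .re_overlap_widths(frames[gi, , drop = FALSE],
                             re_track[re_track$chrom == ch, , drop = FALSE])
    re_frac[gi] <- ov / (frames$end[gi] - frames$start[gi])
  }
  ord <- order(match(vapply(tracks, `[[`, "", "tag"), ALL_TAGS),
               vapply(tracks, `[[`, "", "cell_line"))
  out <- lapply(tracks[ord], function(t) {
    .score_track(genes, frames, t, re_track, min_overlap, normalize, re_frac)
  })
  do.call(rbind, out)
}
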