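# Readers/writers for the plain-text formats the pipeline touches.
# All genomic coordinates are 0-based half-open (BED convention); the gene
# annotation's tss column uses the same convention so one convention holds
# across the package.

#' Read a BED file of genomic intervals
#'
#' Parses 3+ column BED. Coordinates are kept 0-based half-open and
#' intervals are returned in file order (no implicit sorting). Column 4,
#' when present, becomes the interval name.
#'
#' @param path Path to a tab-separated BED file.
#' @return A data.frame with columns `chrom`, `start`, `end` and (if the
#'   file has a 4th column) `name`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t50\t250\tAluY", f)
#' read_bed(f)
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("BED parse error at line ", which(nf < 3L)[1L],
         ": fewer than 3 tab-separated fields")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end))
  if (length(bad)) {
    stop("BED parse error at line ", bad[1L], ": non-integer coordinates")
  }
  bad <- which(start < 0 | start >= end)
  if (length(bad)) {
    stop("BED parse error at line ", bad[1L],
         ": invalid interval (need 0 <= start < end)")
  }
  bad <- which(!nzchar(chrom))
  if (length(bad)) {
    stop("BED parse error at line ", bad[1L], ": empty chromosome name")
  }
  out <- data.frame(chrom = chrom, start = as.integer(start),
                    end = as.integer(end), stringsAsFactors = FALSE)
  if (any(nf >= 4L)) {
    out$name <- vapply(fields, function(x) if (length(x) >= 4L) x[[4L]] else "", "")
  }
  out
}

#' Write intervals to a BED file
#'
#' Inverse of [read_bed()]: writing the data.frame returned by `read_bed`
#' reproduces a canonical 3/4-column BED byte-for-byte.
#'
#' @param x data.frame with columns `chrom`, `start`, `end`, optional `name`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  cols <- list(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE))
  if (!is.null(x$name)) cols <- c(cols, list(x$name))
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Tab-separated with header columns `gene_id`, `symbol`, `chrom`, `tss`,
#' `strand`. The `tss` coordinate is 0-based. Duplicate gene identifiers
#' and negative TSS coordinates are rejected.
#'
#' @param path Path to the annotation TSV.
#' @return data.frame with one row per gene.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("gene annotation file not found: ", path)
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "symbol", "chrom", "tss", "strand")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("gene annotation is missing columns: ", paste(miss, collapse = ", "))
  }
  x <- x[, need]
  dup <- unique(x$gene_id[duplicated(x$gene_id)])
  if (length(dup)) {
    stop("duplicate gene_id in annotation: ",
         paste(head(dup, 5L), collapse = ", "))
  }
  x$tss <- suppressWarnings(as.numeric(x$tss))
  if (any(is.na(x$tss)) || any(x$tss < 0)) {
    stop("gene annotation: tss must be a non-negative number")
  }
  x$tss <- as.integer(x$tss)
  x
}

#' Read a per-gene dN/dS table
#'
#' Two tab-separated columns with header `gene_id`, `dnds`. Values must be
#' non-negative; the literal `NA` marks a gene without an estimate.
#'
#' @param path Path to the TSV.
#' @return Named numeric vector (names are gene identifiers).
#' @export
read_dnds <- function(path) {
  if (!file.exists(path)) stop("dN/dS file not found: ", path)
  x <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "dnds") %in% names(x))) {
    stop("dN/dS table needs columns gene_id, dnds")
  }
  v <- as.numeric(x$dnds)
  if (any(v < 0, na.rm = TRUE)) stop("dN/dS values must be >= 0")
  if (anyDuplicated(x$gene_id)) stop("duplicate gene_id in dN/dS table")
  stats::setNames(v, x$gene_id)
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then member symbols, tab-separated.
#' Duplicate members within a line are collapsed.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors of member symbols, with a
#'   `description` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character()
  if (length(lines)) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L)) {
      stop("GMT parse error at line ", which(nf < 3L)[1L],
           ": need name, description and at least one member")
    }
    nm <- vapply(fields, `[[`, "", 1L)
    if (anyDuplicated(nm)) {
      stop("GMT: duplicate pathway id ", nm[duplicated(nm)][1L])
    }
    sets <- lapply(fields, function(x) unique(x[-(1:2)]))
    names(sets) <- nm
    desc <- stats::setNames(vapply(fields, `[[`, "", 2L), nm)
  }
  structure(sets, description = desc)
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors; an optional `description`
#'   attribute supplies the second column (default `"na"`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read pathway topology tables
#'
#' `nodes_path`: TSV with columns `pathway_id`, `node_id`, `gene` (one row
#' per node member). `edges_path`: TSV with columns `pathway_id`, `source`,
#' `target`, `label`. Node identity is scoped to its pathway.
#'
#' @param nodes_path,edges_path Paths to the two TSV files.
#' @return list with data.frames `nodes` and `edges`.
#' @export
read_topology <- function(nodes_path, edges_path) {
  nodes <- read.delim(nodes_path, stringsAsFactors = FALSE)
  edges <- read.delim(edges_path, stringsAsFactors = FALSE)
  if (!all(c("pathway_id", "node_id", "gene") %in% names(nodes))) {
    stop("nodes table needs columns pathway_id, node_id, gene")
  }
  if (!all(c("pathway_id", "source", "target", "label") %in% names(edges))) {
    stop("edges table needs columns pathway_id, source, target, label")
  }
  known <- paste(nodes$pathway_id, nodes$node_id)
  bad <- !(paste(edges$pathway_id, edges$source) %in% known &
             paste(edges$pathway_id, edges$target) %in% known)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("edge references unknown node: ", edges$pathway_id[i], " ",
         edges$source[i], " -> ", edges$target[i])
  }
  list(nodes = nodes, edges = edges)
}

#' Read a two-column term annotation table
#'
#' TSV with header `term_id`, `gene_id`; returns the term -> gene-set list
#' used by [hypergeometric_enrichment()].
#'
#' @param path Path to the TSV.
#' @return Named list of character vectors.
#' @export
read_term_annotations <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("term_id", "gene_id") %in% names(x))) {
    stop("term annotation table needs columns term_id, gene_id")
  }
  lapply(split(x$gene_id, x$term_id), unique)
}

#' Write a score table
#'
#' Tab-separated with header; missing values written as literal `NA`.
#' Numeric values survive a write/read round trip to at least 12
#' significant digits.
#'
#' @param scores data.frame; first column identifies the entity.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_score_table <- function(scores, path) {
  stopifnot(is.data.frame(scores))
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a score table written by [write_score_table()]
#' @param path Path to the TSV.
#' @return data.frame.
#' @export
read_score_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
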