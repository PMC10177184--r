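re_df <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(chrom = "chr1", start = m[, 1], end = m[, 2])
}

test_that("TSS frames are centered, clipped at zero, and validated", {
  f <- build_tss_frame(list(chrom = "chr1", tss = 100000))
  expect_equal(c(f$start, f$end), c(95000L, 105000L))
  f <- build_tss_frame(list(chrom = "chr1", tss = 2000))
  expect_equal(c(f$start, f$end), c(0L, 7000L))
  expect_error(build_tss_frame(list(chrom = "chr1", tss = 1), 0), "frame_size")
  expect_error(build_tss_frame(list(chrom = "chr1", tss = 1), 999), "even")
})

test_that("RE-linkage counts overlaps against the RE union, half-open", {
  el <- re_df(100, 200, 300, 400)
  expect_equal(classify_re_linked(el, re_df(150, 160)),
               list(n_total = 2L, n_re_linked = 1L))
  # touching intervals share no base under the half-open convention
  expect_equal(classify_re_linked(re_df(100, 200), re_df(200, 300)),
               list(n_total = 1L, n_re_linked = 0L))
  # min_overlap applies to total shared bases with the union
  expect_equal(classify_re_linked(re_df(100, 200), re_df(190, 300),
                                  min_overlap = 11)$n_re_linked, 0L)
  expect_equal(classify_re_linked(re_df(100, 200), re_df(190, 300),
                                  min_overlap = 10)$n_re_linked, 1L)
  expect_error(classify_re_linked(el, re_df(1, 2), min_overlap = 0),
               "min_overlap")
})

test_that("RE coverage fraction merges overlapping retroelements", {
  frame <- data.frame(chrom = "chr1", start = 0L, end = 10000L)
  expect_equal(re_coverage_fraction(frame, re_df(50, 250, 8950, 9150)), 0.04)
  expect_equal(re_coverage_fraction(frame, re_df(0, 6000, 4000, 10000)), 1)
  expect_equal(re_coverage_fraction(frame, re_df(1, 2)[0, ]), 0)
  # overlapping REs are not double counted
  expect_equal(re_coverage_fraction(frame, re_df(0, 100, 50, 150)), 0.015)
})

test_that("gene NGRE matches the worked example and degenerate cases", {
  gene <- list(gene_id = "G1", chrom = "chr1", tss = 5000L)
  re <- re_df(50, 250, 8950, 9150)
  tr <- regulatory_track("H3K4me3", "K562",
                         re_df(100, 200, 1000, 1100, 4000, 4100, 9000, 9100))
  s <- compute_gene_ngre(gene, tr, re)
  expect_equal(s$n_total, 4L)
  expect_equal(s$n_re_linked, 2L)
  expect_equal(s$re_fraction, 0.04)
  expect_equal(s$ngre, 12.5)
  expect_false(s$is_zero)
  # no elements in frame
  s0 <- compute_gene_ngre(gene, regulatory_track("TFBS", "K562", re_df(1, 2)[0, ]), re)
  expect_equal(s0$ngre, 0)
  expect_true(s0$is_zero)
  # REs tile the frame: every element linked, ngre = 1
  s1 <- compute_gene_ngre(gene, tr, re_df(0, 10000))
  expect_equal(s1$ngre, 1)
  # RE-free frame with elements present scores 0, not an error
  s2 <- compute_gene_ngre(gene, tr, re_df(1, 2)[0, ])
  expect_equal(s2$ngre, 0)
  expect_false(s2$is_zero)
  # unnormalized score is the plain linked fraction
  expect_equal(compute_gene_ngre(gene, tr, re, normalize = FALSE)$ngre, 0.5)
})

test_that("interval NGRE equals the per-base oracle on random toy frames", {
  set.seed(11)
  for (i in 1:25) {
    toy <- random_toy_frame(40, 20)
    gene <- list(gene_id = "G", chrom = "chrT",
                 tss = toy$frame$start + 5000L)
    tr <- regulatory_track("TFBS", "CL", toy$elements)
    got <- compute_gene_ngre(gene, tr, toy$re)
    want <- oracle_gene_ngre(toy$frame, toy$elements, toy$re)
    expect_identical(got$n_total, want$n_total)
    expect_identical(got$n_re_linked, want$n_re_linked)
    expect_equal(got$re_fraction, want$re_fraction, tolerance = 0)
    expect_equal(got$ngre, want$ngre, tolerance = 0)
  }
})

test_that("the NGRE matrix is complete, order-invariant and compositional", {
  set.seed(3)
  genes <- data.frame(gene_id = sprintf("G%02d", 1:10), symbol = sprintf("G%02d", 1:10),
                      chrom = "chr1", tss = 5000 + (0:9) * 12000,
                      strand = "+", stringsAsFactors = FALSE)
  re <- data.frame(chrom = "chr1",
                   start = sort(sample(0:120000, 60)))
  re$end <- re$start + sample(100:900, 60, replace = TRUE)
  mk <- function(tag, cl) {
    s <- sample(0:120000, 120)
    regulatory_track(tag, cl, data.frame(chrom = "chr1", start = s, end = s + 200))
  }
  tracks <- list(mk("H3K4me3", "A"), mk("H3K4me3", "B"), mk("H3K4me3", "C"),
                 mk("H3K9me3", "A"), mk("H3K9me3", "B"), mk("H3K9me3", "C"))
  m1 <- compute_ngre_matrix(genes, tracks, re)
  expect_equal(nrow(m1), 60L)  # 10 genes x 2 tags x 3 lines
  m2 <- compute_ngre_matrix(genes, rev(tracks), re)
  expect_identical(m1, m2)
  # matrix equals cell-wise single-gene scoring
  for (i in c(1L, 17L, 60L)) {
    row <- m1[i, ]
    tr <- tracks[[which(vapply(tracks, function(t)
      t$tag == row$tag && t$cell_line == row$cell_line, TRUE))]]
    gene <- genes[genes$gene_id == row$gene_id, ]
    single <- compute_gene_ngre(gene, tr, re)
    expect_equal(row$ngre, single$ngre)
    expect_equal(row$n_total, single$n_total)
  }
  expect_error(compute_ngre_matrix(genes, tracks[c(1, 1)], re), "duplicate")
})

test_that("adding a retroelement never decreases linkage or coverage", {
  set.seed(21)
  toy <- random_toy_frame(30, 15)
  gene <- list(gene_id = "G", chrom = "chrT", tss = toy$frame$start + 5000L)
  tr <- regulatory_track("TFBS", "CL", toy$elements)
  base <- compute_gene_ngre(gene, tr, toy$re)
  for (i in 1:10) {
    extra <- data.frame(chrom = "chrT", start = toy$frame$start + i * 37,
                        end = toy$frame$start + i * 37 + 400)
    more <- compute_gene_ngre(gene, tr, rbind(toy$re, extra))
    expect_gte(more$n_re_linked, base$n_re_linked)
    expect_gte(more$re_fraction, base$re_fraction)
  }
})

test_that("NGRE is invariant under doubling all coordinates", {
  set.seed(31)
  toy <- random_toy_frame(40, 20)
  gene <- list(gene_id = "G", chrom = "chrT", tss = toy$frame$start + 5000L)
  tr <- regulatory_track("TFBS", "CL", toy$elements)
  a <- compute_gene_ngre(gene, tr, toy$re)
  dbl <- function(df) transform(df, start = 2L * start, end = 2L * end)
  gene2 <- list(gene_id = "G", chrom = "chrT", tss = 2L * (toy$frame$start + 5000L))
  tr2 <- regulatory_track("TFBS", "CL", dbl(toy$elements))
  b <- compute_gene_ngre(gene2, tr2, dbl(toy$re), frame_size = 20000)
  expect_equal(b$ngre, a$ngre)
  expect_equal(b$n_re_linked, a$n_re_linked)
})
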