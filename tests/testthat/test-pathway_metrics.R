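test_that("pathway dN/dS is the mean over members with values", {
  dnds <- c(A = 0.1, B = 0.3, C = 0.7, D = NA)
  expect_equal(pathway_dnds(c("A", "B"), dnds)$dnds_pw, 0.2)
  expect_equal(pathway_dnds("C", dnds)$dnds_pw, 0.7)
  r <- pathway_dnds(c("A", "D", "ZZZ"), dnds)
  expect_equal(r$dnds_pw, 0.1)
  expect_equal(r$n_genes_matched, 1L)
  expect_equal(r$n_excluded, 2L)
  expect_true(is.na(pathway_dnds(c("D", "ZZZ"), dnds)$dnds_pw))
})

test_that("a union of two disjoint equal-size sets averages their dN/dS", {
  set.seed(8)
  dnds <- setNames(rexp(40, 4), sprintf("G%02d", 1:40))
  a <- names(dnds)[1:20]; b <- names(dnds)[21:40]
  expect_equal(pathway_dnds(c(a, b), dnds)$dnds_pw,
               mean(c(pathway_dnds(a, dnds)$dnds_pw,
                      pathway_dnds(b, dnds)$dnds_pw)))
})

test_that("NPII is member mean over background mean with neutral value 1", {
  profile <- setNames(c(2, 4, 6, 8), c("A", "B", "C", "D"))
  expect_equal(pathway_npii(names(profile), profile), 1)
  expect_equal(pathway_npii(c("C", "D"), profile), 7 / 5)
  expect_equal(pathway_npii(c("A", "B", "C", "D", "A"), profile), 1)
  expect_equal(pathway_npii("B", profile, normalize = FALSE), 4)
  expect_true(is.na(pathway_npii("ZZZ", profile)))
  expect_equal(pathway_npii(c("A", "B"),
                            setNames(c(0, 0, 4, 4), names(profile))), 0)
  expect_error(pathway_npii("A", setNames(rep(0, 4), names(profile))),
               "background")
})

test_that("NPII normalization identity holds per profile in the matrix", {
  set.seed(9)
  genes <- sprintf("G%02d", 1:40)
  v <- setNames(rexp(40), genes)
  long <- full_tag_long(v, n_cells = 2)
  npii <- compute_npii_matrix(list(ALL = genes), long)
  expect_equal(npii$npii, rep(1, nrow(npii)))
})

test_that("pathway aggregation mirrors the gene-level rules", {
  set.seed(10)
  genes <- sprintf("G%02d", 1:30)
  v <- setNames(c(rexp(24), rep(0, 6)), genes)
  long <- full_tag_long(v, n_cells = 3)
  weights <- compute_cell_line_weights(long)
  pw <- list(P1 = genes[1:10], P2 = genes[11:30])
  npii <- compute_npii_matrix(pw, long)
  agg <- aggregate_pathway_scores(npii, weights)
  # identical npii across profiles within a pathway passes through
  expect_equal(agg$NPII_AGG[agg$pathway_id == "P1"],
               mean(v[1:10]) / mean(v), tolerance = 1e-12)
  # classes combine as (hc + ac + tfbs)/3
  expect_equal(agg$NPII_AGG, (agg$NPII_hc + agg$NPII_ac + agg$NPII_TFBS) / 3)
})

test_that("pathway scores join the two axes and flag unscorable pathways", {
  set.seed(12)
  genes <- sprintf("G%02d", 1:20)
  v <- setNames(rexp(20), genes)
  long <- full_tag_long(v, n_cells = 1)
  dnds <- setNames(runif(20), genes)
  dnds[1:10] <- NA
  pw <- list(OK = genes[11:20], NODNDS = genes[1:10], EMPTY = c("X1", "X2"))
  expect_message(
    ps <- compute_pathway_scores(pw, long, dnds, compute_cell_line_weights(long)),
    "unscorable")
  expect_equal(ps$n_genes_matched[ps$pathway_id == "OK"], 10L)
  expect_true(is.na(ps$dnds_pw[ps$pathway_id == "NODNDS"]))
  expect_true(is.na(ps$NPII_AGG[ps$pathway_id == "EMPTY"]))
})

test_that("node scores average member genes and flag missing metrics", {
  topo <- list(nodes = data.frame(
    pathway_id = "P1", node_id = c("N1", "N1", "N2", "N3"),
    gene = c("A", "B", "C", "D"), stringsAsFactors = FALSE))
  dnds <- c(A = 0.2, B = 0.4, C = NA, D = 0.9)
  gs <- data.frame(gene_id = c("A", "B", "C", "D"),
                   NGRE_AGG = c(1, 3, 5, NA), stringsAsFactors = FALSE)
  ns <- node_scores(topo, dnds, gs)
  n1 <- ns[ns$node_id == "N1", ]
  expect_equal(n1$node_dnds, 0.3)
  expect_equal(n1$node_ngre_agg, 2)
  n2 <- ns[ns$node_id == "N2", ]
  expect_true(n2$dnds_missing)
  expect_equal(n2$node_ngre_agg, 5)  # other metric still computed
  n3 <- ns[ns$node_id == "N3", ]     # single-gene node: its own values
  expect_equal(n3$node_dnds, 0.9)
  expect_true(n3$ngre_missing)
  # order of gene listing does not matter
  topo2 <- list(nodes = topo$nodes[c(4, 3, 1, 2), ])
  expect_equal(node_scores(topo2, dnds, gs), ns)
})

test_that("chart export is deterministic and validates edges", {
  topo <- list(nodes = data.frame(
    pathway_id = "P1", node_id = c("N1", "N2", "N3"),
    gene = c("A", "B", "C"), stringsAsFactors = FALSE))
  dnds <- c(A = 0.2, B = 0.4, C = 0.1)
  gs <- data.frame(gene_id = c("A", "B", "C"), NGRE_AGG = 1:3,
                   stringsAsFactors = FALSE)
  ns <- node_scores(topo, dnds, gs)
  edges <- data.frame(source = c("N1", "N2"), target = c("N2", "N3"),
                      label = "activation", stringsAsFactors = FALSE)
  d <- withr::local_tempdir()
  export_pathway_chart(ns, edges, d)
  expect_length(readLines(file.path(d, "nodes.tsv")), 4L)
  expect_length(readLines(file.path(d, "edges.tsv")), 3L)
  before <- tools::md5sum(file.path(d, c("nodes.tsv", "edges.tsv")))
  export_pathway_chart(ns, edges, d)
  expect_identical(tools::md5sum(file.path(d, c("nodes.tsv", "edges.tsv"))),
                   before)
  bad <- rbind(edges, data.frame(source = "N1", target = "N9",
                                 label = "inhibition"))
  expect_error(export_pathway_chart(ns, bad, d), "N9")
})
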