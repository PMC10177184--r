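test_that("the generator is fully determined by its seed", {
  cfg <- tiny_config(seed = 101)
  s1 <- simulate_inputs(cfg)
  s2 <- simulate_inputs(tiny_config(seed = 101))
  expect_identical(s1$re, s2$re)
  expect_identical(s1$dnds, s2$dnds)
  expect_identical(s1$tracks[[5]]$elements, s2$tracks[[5]]$elements)
  expect_identical(s1$pathways, s2$pathways)
  s3 <- simulate_inputs(tiny_config(seed = 102))
  expect_false(identical(s1$re, s3$re))
})

test_that("retroelement coverage hits the configured genome fraction", {
  for (target in c(0.15, 0.3)) {
    cfg <- tiny_config(seed = 55, re_coverage = target)
    reg <- make_regulatory_inputs(cfg)
    L <- cfg$n_genes * cfg$gene_spacing
    cov <- sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(reg$re$start + 1L, reg$re$end)))) / L
    expect_lt(abs(cov - target), 0.011)
  }
})

test_that("overlapping frames and invalid probabilities are rejected", {
  expect_error(synthetic_config(gene_spacing = 8000), "disjoint")
  expect_error(synthetic_config(re_coverage = 1.4), "\\[0, 1\\]")
  expect_error(synthetic_config(n_genes = 10, pathway_size = 50),
               "pathway_size")
})

test_that("planted genes show elevated raw NGRE linkage", {
  cfg <- tiny_config(seed = 77)
  reg <- make_regulatory_inputs(cfg)
  ngre <- compute_ngre_matrix(reg$genes, reg$tracks, reg$re)
  raw <- tapply(ngre$ngre, ngre$gene_id, mean)
  planted <- names(raw) %in% reg$planted
  expect_gt(mean(raw[planted]), mean(raw[!planted]))
  # frame zero rate tracks the configured zero inflation
  expect_lt(abs(mean(ngre$is_zero) - cfg$zero_rate), 0.05)
})

test_that("dN/dS is positive with the configured latent coupling", {
  cfg <- tiny_config(seed = 31, n_genes = 2000L, dnds_missing_rate = 0)
  reg <- make_regulatory_inputs(cfg)
  d1 <- make_dnds(cfg, reg$latent)
  expect_true(all(d1 > 0))
  # rho_latent = 1 makes dN/dS a monotone map of the latent
  cfg1 <- tiny_config(seed = 31, n_genes = 2000L, dnds_missing_rate = 0,
                      rho_latent = 1)
  expect_equal(spearman(make_dnds(cfg1, reg$latent), reg$latent)$rho, 1)
  # rho_latent = 0 decouples the axes (3 standard errors around zero)
  cfg0 <- tiny_config(seed = 31, n_genes = 2000L, dnds_missing_rate = 0,
                      rho_latent = 0)
  expect_lt(abs(spearman(make_dnds(cfg0, reg$latent), reg$latent)$rho),
            3 / sqrt(2000))
})

test_that("pathways partition into connected nonempty nodes", {
  cfg <- tiny_config(seed = 19)
  sim <- simulate_inputs(cfg)
  expect_length(sim$pathways, cfg$n_pathways)
  expect_true(all(lengths(sim$pathways) == cfg$pathway_size))
  nd <- sim$topology$nodes
  for (pw in names(sim$pathways)[1:5]) {
    rows <- nd[nd$pathway_id == pw, ]
    # partition: every member exactly once
    expect_setequal(rows$gene, sim$pathways[[pw]])
    expect_equal(nrow(rows), length(sim$pathways[[pw]]))
    k <- length(unique(rows$node_id))
    expect_true(k >= 3 && k <= 8)
    # spanning construction keeps the node graph connected (undirected)
    ed <- sim$topology$edges[sim$topology$edges$pathway_id == pw, ]
    reach <- unique(rows$node_id)[1]
    repeat {
      nxt <- unique(c(reach, ed$target[ed$source %in% reach],
                      ed$source[ed$target %in% reach]))
      if (length(nxt) == length(reach)) break
      reach <- nxt
    }
    expect_setequal(reach, unique(rows$node_id))
  }
  # planted term annotates exactly the planted genes
  expect_setequal(sim$terms$PLANTED_SET, sim$planted)
})

test_that("written synthetic inputs are complete and re-readable", {
  d <- withr::local_tempdir()
  sim <- simulate_inputs(tiny_config(seed = 23))
  yml <- write_synthetic_inputs(sim, d)
  expect_true(file.exists(yml))
  genes <- read_gene_annotation(file.path(d, "genes.tsv"))
  expect_equal(nrow(genes), 150L)
  re <- read_bed(file.path(d, "re.bed"))
  expect_equal(nrow(re), nrow(sim$re))
  gmt <- read_gmt(file.path(d, "pathways.gmt"))
  expect_equal(length(gmt), 20L)
  expect_equal(unname(lengths(gmt)), rep(15L, 20L))
  tr <- read_score_table(file.path(d, "tracks.tsv"))
  expect_equal(nrow(tr), 6 * 2 + 2)
  expect_true(all(file.exists(file.path(d, tr$path))))
})
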