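test_that("region classification follows genic > regulatory > intergenic", {
  g_len <- c(c1 = 500L)
  genes <- data.frame(contig = "c1", start = 100L, end = 200L, strand = "+",
                      gene_id = "g1")
  part <- classify_regions(g_len, genes, R = 100)
  expect_equal(unname(classify_positions(part, "c1", c(0, 99))),
               c("regulatory", "regulatory"))
  expect_equal(unname(classify_positions(part, "c1", c(100, 199))),
               c("genic", "genic"))
  expect_equal(unname(classify_positions(part, "c1", c(200, 499))),
               c("intergenic", "intergenic"))
  expect_equal(unname(part$lengths),
               c(100, 100, 300))
})

test_that("minus-strand regulatory windows sit on the 3' genomic side", {
  g_len <- c(c1 = 500L)
  genes <- data.frame(contig = "c1", start = 100L, end = 200L, strand = "-",
                      gene_id = "g1")
  part <- classify_regions(g_len, genes, R = 50)
  expect_equal(unname(classify_positions(part, "c1", c(200, 249))),
               c("regulatory", "regulatory"))
  expect_equal(unname(classify_positions(part, "c1", 250)), "intergenic")
  expect_equal(unname(classify_positions(part, "c1", 99)), "intergenic")
})

test_that("upstream windows truncate at contig edges and neighbouring genes", {
  g_len <- c(c1 = 300L)
  genes <- data.frame(contig = "c1", start = c(30L, 120L), end = c(110L, 200L),
                      strand = "+", gene_id = c("g1", "g2"))
  part <- classify_regions(g_len, genes, R = 100)
  # g1's window truncates at the contig start; g2's at g1's body
  expect_equal(unname(classify_positions(part, "c1", c(0, 29))),
               c("regulatory", "regulatory"))
  expect_equal(unname(classify_positions(part, "c1", c(110, 119))),
               c("regulatory", "regulatory"))
  expect_equal(unname(classify_positions(part, "c1", 109)), "genic")
  # R = 0 removes the regulatory class entirely
  part0 <- classify_regions(g_len, genes, R = 0)
  expect_equal(unname(part0$lengths["regulatory"]), 0)
})

test_that("region lengths always partition the genome", {
  set.seed(71)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    len <- sample(100:300, 1)
    L <- n * len + sample(500:3000, 1)
    iv <- metaepi:::place_genes_uniform(n, len, L)
    genes <- data.frame(contig = "c1", start = iv[, 1], end = iv[, 2],
                        strand = sample(c("+", "-"), n, replace = TRUE),
                        gene_id = paste0("g", 1:n))
    part <- classify_regions(c(c1 = L), genes, R = sample(c(0, 50, 100), 1))
    expect_equal(sum(part$lengths), L)
  }
})

test_that("region densities use the methylated-base coordinate", {
  g_len <- c(c1 = 1000L)
  genes <- data.frame(contig = "c1", start = 0L, end = 500L, strand = "+",
                      gene_id = "g1")
  part <- classify_regions(g_len, genes, R = 0)
  sites <- data.frame(contig = "c1", meth_pos = c(10L, 250L, 700L, 800L))
  rd <- region_density(sites, part)
  expect_equal(rd$density[rd$region == "genic"], 2 * 1000 / 500)
  expect_equal(rd$density[rd$region == "intergenic"], 2 * 1000 / 500)
  expect_true(is.na(rd$density[rd$region == "regulatory"]))
  expect_equal(sum(rd$length_bp), 1000)
})

test_that("uniform non-overlapping gene placement is valid and exhaustive", {
  set.seed(72)
  for (i in 1:50) {
    n <- sample(1:20, 1)
    len <- sample(50:200, 1)
    L <- n * len + sample(0:5000, 1)
    iv <- metaepi:::place_genes_uniform(n, len, L)
    expect_equal(nrow(iv), n)
    expect_true(all(iv[, 2] - iv[, 1] == len))
    expect_true(all(iv[, 1] >= 0) && all(iv[, 2] <= L))
    if (n > 1) expect_true(all(iv[-1, 1] >= iv[-n, 2]))
  }
  expect_error(metaepi:::place_genes_uniform(10, 100, 500), "infeasible")
})

test_that("the shuffle null is deterministic under a fixed seed", {
  cfg <- small_config(seed = 12, plant_rate = 3)
  sim <- simulate_genome(cfg)
  nd1 <- shuffle_null(sim$genome, sim$genes, sim$truth$sites, n = 120, seed = 4)
  nd2 <- shuffle_null(sim$genome, sim$genes, sim$truth$sites, n = 120, seed = 4)
  expect_identical(nd1$null, nd2$null)
  nd3 <- shuffle_null(sim$genome, sim$genes, sim$truth$sites, n = 120, seed = 5)
  expect_false(identical(nd1$null, nd3$null))
})

test_that("a genome without genes is entirely intergenic in every replicate", {
  g <- genome("g", c(c1 = random_dna(3000, seed = 73)))
  genes <- data.frame(contig = character(0), start = integer(0), end = integer(0),
                      strand = character(0), gene_id = character(0))
  sites <- scan_motif(g, motif_spec("GATC", 1))
  nd <- shuffle_null(g, genes, sites, n = 120, seed = 1)
  # genic and regulatory regions have zero length, so their densities
  # are undefined, and the intergenic density is fixed at the observed
  expect_true(all(is.na(nd$null[, "genic"])))
  expect_true(all(is.na(nd$null[, "regulatory"])))
  expect_true(all(nd$null[, "intergenic"] == nd$observed[["intergenic"]]))
})

test_that("enrichment test takes the z path on normal nulls", {
  nd <- structure(list(
    observed = c(regulatory = 5, genic = 5, intergenic = 5),
    null = cbind(regulatory = rnorm(500, 5, 1), genic = rnorm(500, 5, 1),
                 intergenic = rnorm(500, 5, 1)),
    shapiro_p = c(regulatory = 0.5, genic = 0.5, intergenic = 0.5),
    n = 500L, R = 100), class = "null_distribution")
  set.seed(74)
  nd$null <- cbind(regulatory = rnorm(500, 5, 1), genic = rnorm(500, 5, 1),
                   intergenic = rnorm(500, 5, 1))
  et <- enrichment_test(nd)
  expect_true(all(et$method == "z"))
  expect_true(all(abs(et$z) < 0.2))
  expect_true(all(et$p > 0.8))

  # observed at +1.96 sd: p ~ 0.05
  nd$observed["genic"] <- mean(nd$null[, "genic"]) + 1.96 * sd(nd$null[, "genic"])
  et2 <- enrichment_test(nd)
  expect_equal(et2$p[et2$region == "genic"], 0.05, tolerance = 0.01)
})

test_that("skewed nulls fall back to the empirical branch", {
  set.seed(75)
  sk <- rexp(500, 1)^2
  nd <- structure(list(
    observed = c(regulatory = max(sk) * 1.2, genic = mean(sk), intergenic = mean(sk)),
    null = cbind(regulatory = sk, genic = sk, intergenic = sk),
    shapiro_p = c(regulatory = shapiro.test(sk)$p.value,
                  genic = shapiro.test(sk)$p.value,
                  intergenic = shapiro.test(sk)$p.value),
    n = 500L, R = 100), class = "null_distribution")
  et <- enrichment_test(nd)
  expect_true(all(et$method == "empirical"))
  expect_lt(et$p[et$region == "regulatory"], 0.01)
  expect_error(enrichment_test(structure(list(n = 50L), class = "null_distribution")),
               "100")
})

test_that("a planted-uniform motif is not called enriched", {
  cfg <- small_config(seed = 14, plant_rate = 3)
  sim <- simulate_genome(cfg)
  nd <- shuffle_null(sim$genome, sim$genes, sim$truth$sites, n = 200, seed = 2)
  et <- enrichment_test(nd)
  expect_true(all(et$p > 0.01, na.rm = TRUE))
})
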