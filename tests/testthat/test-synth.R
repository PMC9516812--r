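test_that("config validation rejects impossible designs", {
  expect_error(synth_config(genome_length = 1000, genes_per_strand = 10,
                            gene_mean_length = 200), "infeasible")
  expect_error(synth_config(h0 = 1.2))
  expect_error(synth_config(mu_m = 0.8), "mu_m")
  expect_error(synth_config(n_samples = 1))
  expect_error(synth_config(depletion_factor = 0))
})

test_that("a fixed seed reproduces the corpus byte for byte", {
  cfg <- small_config(seed = 91, n_loci = 60)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- simulate_corpus(cfg, d1)
  p2 <- simulate_corpus(cfg, d2)
  for (nm in names(p1)) {
    expect_identical(unname(tools::md5sum(p1[[nm]])), unname(tools::md5sum(p2[[nm]])),
                     info = nm)
  }
  # and a different seed changes the genome
  d3 <- withr::local_tempdir()
  p3 <- simulate_corpus(small_config(seed = 92, n_loci = 60), d3)
  expect_false(identical(unname(tools::md5sum(p1[["genome"]])),
                         unname(tools::md5sum(p3[["genome"]]))))
})

test_that("every emitted file is readable by the package's typed readers", {
  cfg <- small_config(seed = 93, n_loci = 60)
  d <- withr::local_tempdir()
  p <- simulate_corpus(cfg, d)
  g <- read_fasta(p[["genome"]])
  expect_equal(genome_length(g), cfg$genome_length)
  genes <- read_gene_table(p[["genes"]], "gff3")
  expect_equal(nrow(genes), 2 * cfg$genes_per_strand)
  ac <- read_allele_counts(p[["allele_counts"]])
  expect_setequal(unique(ac$sample), paste0("St", 1:cfg$n_samples))
  hits <- read_hits_table(p[["hits"]])
  expect_true(all(hits$bit_score >= 0))
  ph <- read_fasta(p[["phages"]], kingdom = "virus")
  expect_equal(length(ph$contigs), sum(cfg$phage_n_per_clade))
  truth <- jsonlite::read_json(p[["truth"]])
  expect_equal(truth$h0, cfg$h0)
})

test_that("planted sites carry the no-noise limits of the truth model", {
  # h0 = 0: every methylated locus has true fraction exactly 1
  cfg <- small_config(seed = 94, h0 = 0, meth_prob = 1)
  sim <- simulate_genome(cfg)
  expect_true(all(sim$truth$sites$true_frac == 1))
  # gradient active: fractions fall inside [1 - h0/2, 1] on methylated loci
  cfg2 <- small_config(seed = 95, h0 = 0.6, meth_prob = 1)
  sim2 <- simulate_genome(cfg2)
  expect_true(all(sim2$truth$sites$true_frac >= 1 - 0.6 / 2 - 1e-12))
  expect_true(all(sim2$truth$sites$true_frac <= 1))
  # ori-proximal sites sit lower than ter-proximal sites
  ot <- structure(list(ori = sim2$truth$ori, ter = sim2$truth$ter,
                       circular = TRUE, length = cfg2$genome_length),
                  class = "ori_ter")
  d <- relative_position(sim2$truth$sites$meth_pos, ot)
  expect_lt(mean(sim2$truth$sites$true_frac[d < 0.2]),
            mean(sim2$truth$sites$true_frac[d > 0.8]))
})

test_that("planted density equals the scanned density", {
  cfg <- small_config(seed = 96, plant_rate = 2)
  sim <- simulate_genome(cfg)
  sites <- scan_motif(sim$genome, motif_spec(cfg$motif, cfg$meth_offset))
  expect_equal(nrow(sites), nrow(sim$truth$sites))
  expect_equal(sim$truth$density, nrow(sites) * 1000 / cfg$genome_length)
  # palindromic planting: two strand-sites per planted locus
  expect_equal(nrow(sites), 2 * round(cfg$plant_rate * cfg$genome_length / 1000))
})

test_that("IPD observations honour the control and saturated limits", {
  cfg <- small_config(seed = 97)
  set.seed(1)
  # f = 0: sample mean near the control mean
  x0 <- draw_site_ipd(10000, 0, mu_m = cfg$mu_m, sigma = cfg$sigma0)
  expect_equal(mean(x0), 1, tolerance = 0.02)
  # f = 1, mu_m = 4: sample mean near 4
  x1 <- draw_site_ipd(10000, 1, mu_m = 4, sigma = cfg$sigma_m)
  expect_equal(mean(x1), 4, tolerance = 0.05)
  # f = 0.5 at n = 10000: moment estimator within +-0.02
  x5 <- draw_site_ipd(10000, 0.5, mu_m = 4, sigma = 0.35)
  expect_equal(estimate_fraction(x5, control_model(1, 0.35), 4), 0.5,
               tolerance = 0.02)
})

test_that("simulated calls recover the planted methylation probability", {
  cfg <- small_config(seed = 98, plant_rate = 4, depth_mean = 80)
  sim <- simulate_genome(cfg)
  obs <- simulate_ipd_observations(sim, cfg)
  ann <- annotate_sites(sim$truth$sites, obs$calls)
  r <- motif_methylation_ratio(ann$status[ann$sample == "St1"])
  n <- r$n_eval
  se <- sqrt(cfg$meth_prob * (1 - cfg$meth_prob) / n)
  expect_lt(abs(r$ratio - cfg$meth_prob), 4 * se + 0.02)
})

test_that("population truth stores the analytic F_ST of the designed groups", {
  cfg <- small_config(seed = 99, n_loci = 120, divergence = 0.6, n_samples = 4)
  pop <- simulate_population(cfg)
  tr <- pop$truth
  expect_equal(tr$fst_groups,
               fst_from_frequencies(tr$freq_A, tr$freq_B), tolerance = 1e-12)
  # within-group pairs have zero true divergence, between-group pairs the
  # group value
  s <- tr$samples
  g <- tr$group
  within <- tr$fst[s[g == "A"][1], s[g == "A"][2]]
  between <- tr$fst[s[g == "A"][1], s[g == "B"][1]]
  expect_equal(within, 0)
  expect_equal(between, tr$fst_groups)
})

test_that("degenerate population designs give the boundary F_ST values", {
  cfg0 <- small_config(seed = 100, divergence = 0, n_loci = 50)
  expect_equal(simulate_population(cfg0)$truth$fst_groups, 0)
  cfg1 <- small_config(seed = 101, divergence = 2, n_loci = 50)
  # clamped to 0 vs 1 at every locus: fixed differences
  expect_equal(simulate_population(cfg1)$truth$fst_groups, 1)
})

test_that("phage sets express the configured depletion and hit symmetry", {
  cfg <- synth_config(seed = 102, phage_n_per_clade = c(6, 6),
                      phage_length = 3000, phage_rate = 4,
                      depletion_factor = 0.2)
  ph <- simulate_phage_set(cfg)
  cl <- ph$truth$clade
  # planted per-kb locus rates: depleted = rate * factor
  expect_equal(unique(ph$truth$planted_rate[cl == "normal"]), 4)
  expect_equal(unique(ph$truth$planted_rate[cl == "depleted"]), 0.8)
  # realized strand-site densities reflect the depletion
  expect_gt(median(ph$truth$density[cl == "normal"]),
            3 * median(ph$truth$density[cl == "depleted"]))
  # pair sums are symmetric by construction
  bs <- bitscore_sums(ph$hits)
  expect_equal(bs$sums, t(bs$sums))
  # and the Dice distances hit the designed targets
  dd <- dice_distance(bs)
  ids_n <- names(cl)[cl == "normal"]; ids_d <- names(cl)[cl == "depleted"]
  expect_equal(unname(dd[ids_n[1], ids_n[2]]), cfg$d_within, tolerance = 1e-9)
  expect_equal(unname(dd[ids_n[1], ids_d[1]]), cfg$d_between, tolerance = 1e-9)
})

test_that("a depletion factor of 1 leaves both clades at equal rates", {
  cfg <- synth_config(seed = 103, phage_n_per_clade = c(4, 4),
                      phage_length = 2000, depletion_factor = 1)
  ph <- simulate_phage_set(cfg)
  expect_equal(unname(ph$truth$planted_rate[ph$truth$clade == "normal"]),
               unname(ph$truth$planted_rate[ph$truth$clade == "depleted"]))
})
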