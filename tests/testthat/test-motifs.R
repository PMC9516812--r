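test_that("motif specs validate their IUPAC string and offset", {
  expect_error(motif_spec("GAXTC", 1), "invalid IUPAC")
  expect_error(motif_spec("GANTC", 5), "meth_offset")
  ms <- motif_spec("gantc", 1)
  expect_equal(ms$iupac, "GANTC")
})

test_that("scanning finds degenerate matches on both strands", {
  # GAATC matches GANTC forward; its revcomp GATTC also matches GANTC,
  # so the minus strand carries a site at the same locus
  s <- scan_motif(c(c1 = "GAATC"), motif_spec("GANTC", 1))
  expect_equal(nrow(s), 2L)
  expect_equal(s$start, c(0L, 0L))
  expect_setequal(s$strand, c("+", "-"))
  # methylated A coordinates: offset 1 forward, mirrored on the reverse
  expect_equal(sort(s$meth_pos), c(1L, 3L))

  # palindrome GATC inside AGATCT: two strand-sites at locus 1
  s2 <- scan_motif(c(c1 = "AGATCT"), motif_spec("GATC", 1))
  expect_equal(nrow(s2), 2L)
  expect_equal(s2$start, c(1L, 1L))
  expect_setequal(s2$strand, c("+", "-"))
})

test_that("overlapping matches are all reported", {
  # AAAA contains 3 overlapping AA occurrences per strand
  s <- scan_motif(c(c1 = "AAAA"), motif_spec("AA", 0))
  expect_equal(sum(s$strand == "+"), 3L)
})

test_that("N in the genome never matches any motif symbol", {
  s <- scan_motif(c(c1 = "GANTC"), motif_spec("GANTC", 1))
  expect_equal(nrow(s), 0L)
  s2 <- scan_motif(c(c1 = "GAATCNGAATC"), motif_spec("GANTC", 1))
  expect_equal(nrow(s2), 4L)
})

test_that("scanning equals the brute-force enumeration oracle", {
  set.seed(11)
  motifs <- c("GANTC", "GATC", "CCWGG", "RGATCY", "TCGCGA", "GGTAG", "AY")
  for (i in 1:60) {
    L <- sample(20:120, 1)
    seq <- paste(sample(c("A", "C", "G", "T", "N"), L, replace = TRUE,
                        prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
    m <- sample(motifs, 1)
    got <- scan_motif(c(x = seq), motif_spec(m, 0))
    want <- oracle_scan(c(x = seq), m)
    expect_equal(got[, c("contig", "start", "strand")], want,
                 ignore_attr = TRUE)
  }
})

test_that("methylation ratio excludes unevaluable sites and flags candidates", {
  st <- c(rep("methylated", 3), "unmethylated", rep("unevaluable", 6))
  r <- motif_methylation_ratio(st)
  expect_equal(r$ratio, 0.75)
  expect_equal(r$n_eval, 4L)
  expect_true(r$candidate)

  # boundary: 0.19 is noise, 0.20 is a candidate
  r19 <- motif_methylation_ratio(c(rep("methylated", 19), rep("unmethylated", 81)))
  expect_false(r19$candidate)
  r20 <- motif_methylation_ratio(c(rep("methylated", 20), rep("unmethylated", 80)))
  expect_true(r20$candidate)

  r_none <- motif_methylation_ratio(rep("unevaluable", 5))
  expect_true(is.na(r_none$ratio))
  expect_false(r_none$candidate)
})

test_that("breadth filter applies kingdom thresholds with strict-less drops", {
  expect_false(breadth_filter(0.19, "prokaryote"))
  expect_true(breadth_filter(0.20, "prokaryote"))
  expect_true(breadth_filter(0.60, "virus"))
  expect_false(breadth_filter(0.59, "virus"))
  expect_true(breadth_filter(0.50, "eukaryote"))
  expect_false(breadth_filter(0.09, "eukaryote"))
  expect_true(breadth_filter(0.20, "giant_virus"))
  expect_error(breadth_filter(0.5, "archaeon"), "kingdom")
})

test_that("5-mer profile counts evaluable centre bases on both strands", {
  g <- genome("g", c(c1 = strrep("A", 30)))
  calls <- make_calls("c1", 5:24, "+", "s1", "methylated", frac = 1)
  prof <- build_5mer_profile(g, calls)
  expect_equal(unname(prof["AAAAA"]), 1)
  expect_equal(sum(!is.na(prof)), 1L)

  # no evaluable positions: all entries missing
  calls2 <- make_calls("c1", 5:10, "+", "s1", "unevaluable")
  prof2 <- build_5mer_profile(g, calls2)
  expect_true(all(is.na(prof2)))

  # minus-strand occurrence contributes the revcomp window
  g3 <- genome("g", c(c1 = "TTGGATCCTT"))
  calls3 <- make_calls("c1", 4L, "-", "s1", "methylated", frac = 1)
  prof3 <- build_5mer_profile(g3, calls3)
  # plus-strand window around position 4 reads GGATC; the minus-strand
  # context is its reverse complement GATCC
  expect_equal(unname(prof3["GATCC"]), 1)
  expect_true(is.na(prof3["GGATC"]))
})

test_that("planted fully methylated GANTC shows up in the matching 5-mers", {
  cfg <- small_config(seed = 5, meth_prob = 1, h0 = 0, plant_rate = 3)
  sim <- simulate_genome(cfg)
  obs <- simulate_ipd_observations(sim, cfg)
  st1 <- obs$calls[obs$calls$sample == "St1", ]
  prof <- build_5mer_profile(sim$genome, st1)
  hot <- names(prof)[!is.na(prof) & prof >= 0.9]
  expect_gt(length(hot), 0)
  # windows centred on the methylated A read NGANT on the site strand
  expect_true(all(grepl("^.GA.T$", hot)))
})

test_that("palindromic pairing distinguishes full, hemi and unevaluable loci", {
  sites <- scan_motif(c(c1 = "TTGAATCTTGACTCTTGAGTCTTGATTCTT"), motif_spec("GANTC", 1))
  expect_equal(nrow(sites), 8L)  # 4 loci x 2 strands
  status_by_locus <- list(
    `2` = c("methylated", "methylated"),      # full
    `9` = c("methylated", "unmethylated"),    # hemi
    `16` = c("unmethylated", "unmethylated"), # unmethylated
    `23` = c("methylated", "unevaluable"))    # unevaluable
  ann <- sites
  ann$sample <- "s1"
  ann$status <- unlist(lapply(sites$start, function(st) NA_character_))
  for (loc in names(status_by_locus)) {
    idx <- which(ann$start == as.integer(loc))
    ann$status[idx] <- status_by_locus[[loc]]
  }
  ann$frac <- ifelse(ann$status == "methylated", 0.9, 0.1)
  paired <- pair_palindromic_sites(ann)
  expect_equal(paired$state[match(c(2, 9, 16, 23), paired$start)],
               c("full", "hemi", "unmethylated", "unevaluable"))
})

test_that("palindromic pairing rejects non-self-complementary motifs", {
  sites <- scan_motif(c(c1 = "TTGGTAGTT"), motif_spec("GGTAG", 0))
  sites$sample <- "s1"; sites$status <- "methylated"; sites$frac <- 0.9
  expect_error(pair_palindromic_sites(sites), "not self-complementary")
  expect_true(is_palindromic_motif("GANTC"))
  expect_false(is_palindromic_motif("GGTAG"))
})

test_that("motif density is per-kb over both strands and split-invariant", {
  # 5 planted occurrences of a non-self-complementary motif in 1 kb
  set.seed(9)
  base <- random_dna(1000)
  base <- metaepi:::remove_motif_occurrences(base, "GGTAG")
  ch <- strsplit(base, "")[[1]]
  for (p in c(100, 300, 500, 700, 900)) ch[p:(p + 4)] <- c("G", "G", "T", "A", "G")
  seq1 <- paste(ch, collapse = "")
  g <- genome("g", c(c1 = seq1))
  expect_equal(motif_density(g, "GGTAG"), 5)
  expect_equal(motif_density(genome("g0", c(c1 = strrep("A", 500))), "GGTAG"), 0)

  # splitting into contigs between sites leaves the density unchanged
  g2 <- genome("g2", c(a = substr(seq1, 1, 600), b = substr(seq1, 601, 1000)))
  expect_equal(motif_density(g2, "GGTAG"), 5)
})

test_that("depletion score is calibrated on Markov sequences and detects removal", {
  set.seed(21)
  scores <- replicate(12, {
    s <- random_dna(8000)
    depletion_score(genome("g", c(c1 = s)), "GANTC")$score
  })
  expect_lt(abs(mean(scores) - 1), 0.15)

  # uniform background: closed-form expected count 2 * (L-4) * (1/4)^4
  s <- random_dna(20000, seed = 3)
  ds <- depletion_score(genome("g", c(c1 = s)), "GANTC")
  expect_equal(ds$expected, 2 * (20000 - 4) * (1 / 4)^4, tolerance = 0.1)

  # all occurrences removed: clear depletion
  s2 <- metaepi:::remove_motif_occurrences(s, "GANTC")
  ds2 <- depletion_score(genome("g", c(c1 = s2)), "GANTC")
  expect_equal(ds2$observed, 0)
  expect_lt(ds2$score, 0.2)
})

test_that("context-motif discovery recovers a planted motif", {
  cfg <- small_config(seed = 8, meth_prob = 1, h0 = 0, plant_rate = 4)
  sim <- simulate_genome(cfg)
  obs <- simulate_ipd_observations(sim, cfg)
  st1 <- obs$calls[obs$calls$sample == "St1", ]
  dc <- discover_context_motifs(sim$genome, st1, k = 7)
  expect_gt(nrow(dc), 0)
  expect_equal(attr(dc, "consensus"), "GANTC")
})

test_that("context-motif discovery returns empty results when unsupported", {
  g <- genome("g", c(c1 = random_dna(2000, seed = 2)))
  none <- make_calls("c1", integer(0), character(0), character(0), character(0))
  expect_warning(dc <- discover_context_motifs(g, none), "too few")
  expect_equal(nrow(dc), 0L)
  few <- make_calls("c1", 10:19, "+", "s1", "methylated", frac = 1)
  expect_warning(dc2 <- discover_context_motifs(g, few), "too few")
  expect_equal(nrow(dc2), 0L)
})
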