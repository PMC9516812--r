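## Synthetic communities with known ground truth for every downstream
## stage: a replicon with planted GC-skew structure, strand-assigned
## genes and methylation motifs; per-molecule IPD kinetics; per-sample
## strain mixtures with known allele frequencies (hence known pi and
## F_ST); an ori->ter hemimethylation gradient; and phage genome sets
## with and without motif depletion plus a consistent bit-score table.
##
## A single integer seed fans out into named substreams so that adding
## a component never reshuffles the draws of another.

#' Synthetic community configuration
#'
#' Defaults emulate the study design this package targets: 10 sampling
#' stations, ~100x per-strand long-read depth at evaluable sites, a
#' CcrM-type GANTC methylome at ~90% methylation with a cell-cycle
#' hemimethylation gradient, and pelagiphage-like genome sets with a
#' motif-depleted clade.
#'
#' @param seed integer master seed.
#' @param genome_length replicon length in bp.
#' @param gc GC content of the background sequence.
#' @param skew_amplitude leading-strand G excess (relative).
#' @param ori_frac replication origin position as a fraction of length.
#' @param genes_per_strand,gene_mean_length gene layout per strand.
#' @param motif,meth_offset,mod_type planted motif (default GANTC, m6A
#'   at the A).
#' @param meth_prob probability that a motif locus is methylated by the
#'   MTase.
#' @param plant_rate planted motif loci per kb (background occurrences
#'   are removed first so the planted density is the true density).
#' @param h0 hemimethylation gradient amplitude in \[0,1\].
#' @param n_samples number of samples (stations).
#' @param depth_mean mean per-strand molecule coverage for IPD draws.
#' @param n_background unmethylated non-motif positions observed per
#'   strand (adds true negatives for calling).
#' @param mu_m,sigma_m modified-base IPD-ratio mean and log-sd.
#' @param sigma0 control IPD-ratio log-sd.
#' @param n_loci,divergence,depth_snv population design: biallelic locus
#'   count, allele-frequency divergence between the two sample groups,
#'   and read depth for allele counts.
#' @param phage_n_per_clade,phage_length,phage_rate,depletion_factor,
#'   d_within,d_between phage-set design: genomes per clade, genome
#'   length, motif rate (per kb) in the normal clade, multiplicative
#'   depletion in the depleted clade, and target within/between Dice
#'   distances for the bit-score table.
#' @return list of class `"synth_config"`.
#' @export
synth_config <- function(seed = 1,
                         genome_length = 50000,
                         gc = 0.4,
                         skew_amplitude = 0.1,
                         ori_frac = 0.25,
                         genes_per_strand = 25,
                         gene_mean_length = 900,
                         motif = "GANTC", meth_offset = 1, mod_type = "m6A",
                         meth_prob = 0.9,
                         plant_rate = 2,
                         h0 = 0.6,
                         n_samples = 10,
                         depth_mean = 100,
                         n_background = 200,
                         mu_m = 4, sigma_m = 0.35, sigma0 = 0.35,
                         n_loci = 1000, divergence = 0.3, depth_snv = 100,
                         phage_n_per_clade = c(10, 10), phage_length = 5000,
                         phage_rate = 4, depletion_factor = 0.2,
                         d_within = 0.2, d_between = 0.7) {
  cfg <- as.list(environment())
  stopifnot(cfg$genome_length > 0, cfg$n_samples >= 2,
            cfg$h0 >= 0, cfg$h0 <= 1,
            cfg$meth_prob >= 0, cfg$meth_prob <= 1,
            cfg$depletion_factor > 0, cfg$depletion_factor <= 1)
  if (cfg$mu_m <= 1) stop("mu_m must exceed the control mean (positive signal)")
  if (cfg$genes_per_strand * cfg$gene_mean_length > cfg$genome_length) {
    stop("infeasible gene placement: total gene length exceeds genome length")
  }
  structure(cfg, class = "synth_config")
}

## draw one random base sequence with per-replichore G/C bias
skewed_sequence <- function(L, gc, amp, ori, ter) {
  at <- (1 - gc) / 2
  p_lead <- c(A = at, C = gc / 2 * (1 - amp), G = gc / 2 * (1 + amp), T = at)
  p_lag <- c(A = at, C = gc / 2 * (1 + amp), G = gc / 2 * (1 - amp), T = at)
  pos <- 0:(L - 1)
  on_lead <- if (ori < ter) pos >= ori & pos < ter else pos >= ori | pos < ter
  s <- character(L)
  s[on_lead] <- sample(names(p_lead), sum(on_lead), replace = TRUE, prob = p_lead)
  s[!on_lead] <- sample(names(p_lag), sum(!on_lead), replace = TRUE, prob = p_lag)
  paste(s, collapse = "")
}

## rewrite bases so the sequence contains no occurrence of the motif on
## either strand (iterative scan-and-break)
remove_motif_occurrences <- function(seq, motif, max_rounds = 20) {
  spec <- if (is.character(motif)) motif_spec(motif, 0L) else motif
  for (round in seq_len(max_rounds)) {
    sites <- scan_motif(c(chr = seq), spec)
    if (nrow(sites) == 0L) return(seq)
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    ## break each match by randomising its first matched base to one
    ## outside the allowed set on the matched strand
    for (i in seq_len(nrow(sites))) {
      pat <- if (sites$strand[i] == "+") spec$iupac else revcomp(spec$iupac)
      allowed <- strsplit(IUPAC_MAP[[substr(pat, 1, 1)]], "")[[1]]
      ch[sites$start[i] + 1] <- sample(setdiff(c("A", "C", "G", "T"), allowed), 1)
    }
    seq <- paste(ch, collapse = "")
  }
  seq
}

## realize a concrete instance of an IUPAC motif
concretize_motif <- function(iupac) {
  paste(vapply(strsplit(iupac, "", fixed = TRUE)[[1]], function(s) {
    b <- strsplit(IUPAC_MAP[[s]], "")[[1]]
    if (length(b) == 1L) b else sample(b, 1)
  }, character(1)), collapse = "")
}

plant_motif <- function(seq, motif, n_sites) {
  spec <- if (is.character(motif)) motif_spec(motif, 0L) else motif
  k <- nchar(spec$iupac)
  L <- nchar(seq)
  if (n_sites == 0L) return(seq)
  iv <- place_genes_uniform(n_sites, k + 2, L)  # +2 bp spacing guard
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(iv))) {
    word <- strsplit(concretize_motif(spec$iupac), "", fixed = TRUE)[[1]]
    ch[(iv[i, 1] + 1):(iv[i, 1] + k)] <- word
  }
  paste(ch, collapse = "")
}

#' Simulate a replicon with genes, GC skew and a planted methylome
#'
#' The emitted truth set records, per planted motif site and strand,
#' the true methylated cell fraction: a locus is methylated with
#' probability `meth_prob`; methylated loci carry the hemimethylation
#' gradient 1 - h0*(1 - d)/2 where d is the relative replichore
#' position (0 at ori, 1 at ter).
#'
#' @param config a [synth_config()].
#' @return list with `genome`, `genes`, `truth` (sites with true_frac,
#'   ori/ter, h0, density).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(substream_seed(config$seed, "genome"))
  L <- config$genome_length
  ori <- round(L * config$ori_frac)
  ter <- (ori + L %/% 2) %% L
  seq <- skewed_sequence(L, config$gc, config$skew_amplitude, ori, ter)
  seq <- remove_motif_occurrences(seq, config$motif)
  n_plant <- round(config$plant_rate * L / 1000)
  seq <- plant_motif(seq, motif_spec(config$motif, config$meth_offset), n_plant)
  g <- genome("synth_genome", c(chr1 = seq), kingdom = "prokaryote")
  ## genes, uniformly placed per strand without overlap
  genes <- do.call(rbind, lapply(c("+", "-"), function(st) {
    iv <- place_genes_uniform(config$genes_per_strand, config$gene_mean_length, L)
    data.frame(contig = "chr1", start = iv[, 1], end = iv[, 2], strand = st,
               gene_id = paste0("g", st, seq_len(nrow(iv))))
  }))
  genes$gene_id <- paste0("gene", seq_len(nrow(genes)))
  ## truth: scan the final sequence (plant-then-count)
  spec <- motif_spec(config$motif, config$meth_offset, config$mod_type)
  sites <- scan_motif(g, spec)
  oriter <- structure(list(ori = ori, ter = ter, circular = TRUE, length = L),
                      class = "ori_ter")
  d <- relative_position(sites$meth_pos, oriter)
  if (is_palindromic_motif(config$motif)) {
    locus <- paste(sites$contig, sites$start)
    u <- unique(locus)
    m_loc <- stats::setNames(stats::rbinom(length(u), 1, config$meth_prob), u)
    m <- m_loc[locus]
  } else {
    m <- stats::rbinom(nrow(sites), 1, config$meth_prob)
  }
  sites$true_meth <- as.logical(m)
  sites$true_frac <- ifelse(sites$true_meth, 1 - config$h0 * (1 - d) / 2, 0)
  truth <- list(ori = ori, ter = ter, h0 = config$h0,
                sites = sites,
                motif = config$motif,
                density = nrow(sites) * 1000 / L,
                meth_prob = config$meth_prob)
  list(genome = g, genes = genes, truth = truth)
}

## lognormal with a prescribed arithmetic mean (so the moment estimator
## of the methylated fraction is unbiased)
rlnorm_mean <- function(n, mean, sdlog) {
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate per-molecule IPD observations for a truth set
#'
#' Per site, strand and sample: coverage is Poisson(`depth_mean`); each
#' molecule is methylated with the site's true fraction; unmethylated
#' molecules draw their IPD ratio from the control law (mean 1, log-sd
#' `sigma0`), methylated molecules from the modified law (mean `mu_m`,
#' log-sd `sigma_m`).  Unmethylated background positions are added as
#' true negatives.
#'
#' @param sim a [simulate_genome()] result.
#' @param config the same [synth_config()].
#' @param samples sample ids (default `St1..StS`).
#' @return list with `ipd` (molecule-level table) and `calls`
#'   ([call_sites()] on it, using the generator's kinetic parameters).
#' @export
simulate_ipd_observations <- function(sim, config,
                                      samples = paste0("St", seq_len(config$n_samples))) {
  stopifnot(inherits(config, "synth_config"))
  if (config$mu_m <= 1) stop("mu_m must exceed the control mean")
  set.seed(substream_seed(config$seed, "ipd"))
  sites <- sim$truth$sites
  L <- genome_length(sim$genome)
  ## background positions away from motif sites
  bg_pool <- setdiff(sample.int(L, min(L, config$n_background * 4)) - 1L,
                     sites$meth_pos)
  bg_pos <- utils::head(bg_pool, config$n_background)
  site_tab <- rbind(
    data.frame(contig = sites$contig, position = sites$meth_pos,
               strand = sites$strand, true_frac = sites$true_frac),
    if (length(bg_pos)) data.frame(contig = sites$contig[1], position = bg_pos,
                                   strand = sample(c("+", "-"), length(bg_pos),
                                                   replace = TRUE),
                                   true_frac = 0)
  )
  out <- vector("list", length(samples))
  for (si in seq_along(samples)) {
    cov <- stats::rpois(nrow(site_tab), config$depth_mean)
    n_m <- stats::rbinom(nrow(site_tab), cov, site_tab$true_frac)
    tot_m <- sum(n_m); tot_u <- sum(cov - n_m)
    ipd_m <- rlnorm_mean(tot_m, config$mu_m, config$sigma_m)
    ipd_u <- rlnorm_mean(tot_u, 1, config$sigma0)
    rows <- rep(seq_len(nrow(site_tab)), cov)
    is_m <- unlist(lapply(seq_len(nrow(site_tab)), function(i) {
      c(rep(TRUE, n_m[i]), rep(FALSE, cov[i] - n_m[i]))
    }))
    ipd <- numeric(length(rows))
    ipd[is_m] <- ipd_m
    ipd[!is_m] <- ipd_u
    out[[si]] <- data.frame(contig = site_tab$contig[rows],
                            position = site_tab$position[rows],
                            strand = site_tab$strand[rows],
                            sample = samples[si],
                            ipd_ratio = ipd)
  }
  ipd <- do.call(rbind, out)
  calls <- call_sites(ipd, control_model(1, config$sigma0), mu_m = config$mu_m)
  list(ipd = ipd, calls = calls)
}

#' Simulate a two-group strain population with known F_ST
#'
#' Biallelic loci with designed group allele frequencies: the first
#' half of the samples form group A, the second half group B, with
#' alternate-allele frequencies separated by `divergence`.  Read counts
#' are binomial at Poisson depth.  The analytic Hudson-style F_ST on
#' the true frequencies is recorded in the truth set.
#'
#' @param config a [synth_config()].
#' @param genome optional [genome()] supplying reference bases.
#' @return list with `allele_counts`, `truth` (per-locus frequencies,
#'   group map, true per-sample-pair F_ST matrix, true pi per sample).
#' @export
simulate_population <- function(config, genome = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(substream_seed(config$seed, "population"))
  S <- config$n_samples
  samples <- paste0("St", seq_len(S))
  group <- stats::setNames(rep(c("A", "B"), c(ceiling(S / 2), floor(S / 2))), samples)
  n_loci <- config$n_loci
  if (!is.null(genome)) {
    L <- genome_length(genome)
    pos <- sort(sample.int(L, min(n_loci, L)) - 1L)
    ref <- strsplit(genome$contigs[[1]], "")[[1]][pos + 1]
    contig <- names(genome$contigs)[1]
    bad <- !ref %in% c("A", "C", "G", "T")
    pos <- pos[!bad]; ref <- ref[!bad]
  } else {
    pos <- seq_len(n_loci) - 1L
    ref <- sample(c("A", "C", "G", "T"), n_loci, replace = TRUE)
    contig <- "chr1"
  }
  n_loci <- length(pos)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                character(1), USE.NAMES = FALSE)
  p0 <- stats::runif(n_loci, 0.1, 0.9)
  pA <- clamp(p0 - config$divergence / 2, 0, 1)
  pB <- clamp(p0 + config$divergence / 2, 0, 1)
  freq <- cbind(A = pA, B = pB)
  rows <- vector("list", S)
  for (si in seq_len(S)) {
    f <- freq[, group[[si]]]
    depth <- stats::rpois(n_loci, config$depth_snv)
    nalt <- stats::rbinom(n_loci, depth, f)
    cnt <- matrix(0L, n_loci, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
    cnt[cbind(seq_len(n_loci), match(ref, colnames(cnt)))] <- depth - nalt
    cnt[cbind(seq_len(n_loci), match(alt, colnames(cnt)))] <-
      cnt[cbind(seq_len(n_loci), match(alt, colnames(cnt)))] + nalt
    rows[[si]] <- data.frame(contig = contig, position = pos, ref = ref,
                             sample = samples[si],
                             nA = cnt[, "A"], nC = cnt[, "C"],
                             nG = cnt[, "G"], nT = cnt[, "T"])
  }
  ac <- do.call(rbind, rows)
  ## analytic truths
  fst_true <- matrix(0, S, S, dimnames = list(samples, samples))
  for (i in seq_len(S - 1)) for (j in (i + 1):S) {
    fst_true[i, j] <- fst_true[j, i] <-
      fst_from_frequencies(freq[, group[[i]]], freq[, group[[j]]])
  }
  pi_true <- vapply(samples, function(sm) {
    f <- freq[, group[[sm]]]
    mean(2 * f * (1 - f))
  }, numeric(1))
  truth <- list(samples = samples, group = group, position = pos,
                ref = ref, alt = alt, freq_A = pA, freq_B = pB,
                fst = fst_true, pi = pi_true,
                fst_groups = fst_from_frequencies(pA, pB))
  list(allele_counts = validate_allele_counts(ac), truth = truth)
}

#' Simulate phage genome sets with and without motif depletion
#'
#' Two clades of genomes: the normal clade carries the motif at
#' `phage_rate` loci per kb, the depleted clade at
#' `phage_rate * depletion_factor`.  A consistent bit-score hits table
#' is emitted whose Dice distances are `d_within` inside a clade and
#' `d_between` across clades.
#'
#' @param config a [synth_config()].
#' @return list with `genomes` (list of [genome()]), `hits`, `truth`
#'   (clade map, true densities).
#' @export
simulate_phage_set <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(substream_seed(config$seed, "phage"))
  n1 <- config$phage_n_per_clade[1]; n2 <- config$phage_n_per_clade[2]
  ids <- c(paste0("phage_normal_", seq_len(n1)),
           paste0("phage_depleted_", seq_len(n2)))
  clade <- stats::setNames(rep(c("normal", "depleted"), c(n1, n2)), ids)
  Lp <- config$phage_length
  rate <- ifelse(clade == "normal", config$phage_rate,
                 config$phage_rate * config$depletion_factor)
  genomes <- lapply(seq_along(ids), function(i) {
    s <- paste(sample(c("A", "C", "G", "T"), Lp, replace = TRUE), collapse = "")
    s <- remove_motif_occurrences(s, config$motif)
    s <- plant_motif(s, motif_spec(config$motif, 0L), round(rate[i] * Lp / 1000))
    genome(ids[i], stats::setNames(s, ids[i]), kingdom = "virus")
  })
  names(genomes) <- ids
  ## bit-score table consistent with the designed Dice distances
  self <- stats::setNames(rep(2 * Lp, length(ids)), ids)
  hits <- data.frame(query = ids, subject = ids, bit_score = self)
  for (i in seq_along(ids)[-length(ids)]) for (j in (i + 1):length(ids)) {
    D <- if (clade[i] == clade[j]) config$d_within else config$d_between
    ab <- (1 - D) * (self[i] + self[j]) / 2
    hits <- rbind(hits,
                  data.frame(query = ids[i], subject = ids[j], bit_score = ab),
                  data.frame(query = ids[j], subject = ids[i], bit_score = ab))
  }
  rownames(hits) <- NULL
  dens <- vapply(genomes, function(g) motif_density(g, config$motif), numeric(1))
  truth <- list(clade = clade,
                planted_rate = stats::setNames(rate, ids),
                density = dens,
                d_within = config$d_within, d_between = config$d_between)
  list(genomes = genomes, hits = hits, truth = truth)
}

#' Write a full synthetic corpus to disk
#'
#' Emits FASTA, GFF3 genes, molecule-level IPD TSV, per-sample
#' modification-call TSV, allele-counts TSV, phage hits TSV and a truth
#' JSON, all readable by the package's readers.
#'
#' @param config a [synth_config()].
#' @param out_dir output directory (created).
#' @return invisible named vector of file paths.
#' @export
simulate_corpus <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_genome(config)
  obs <- simulate_ipd_observations(sim, config)
  pop <- simulate_population(config, sim$genome)
  ph <- simulate_phage_set(config)
  paths <- c(
    genome = file.path(out_dir, "genome.fasta"),
    genes = file.path(out_dir, "genes.gff3"),
    ipd = file.path(out_dir, "ipd.tsv"),
    calls = file.path(out_dir, "calls.tsv"),
    allele_counts = file.path(out_dir, "allele_counts.tsv"),
    hits = file.path(out_dir, "phage_hits.tsv"),
    phages = file.path(out_dir, "phages.fasta"),
    truth = file.path(out_dir, "truth.json"))
  write_fasta(sim$genome, paths[["genome"]])
  write_gene_table(sim$genes, paths[["genes"]])
  utils::write.table(obs$ipd, paths[["ipd"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(obs$calls, paths[["calls"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_allele_counts(pop$allele_counts, paths[["allele_counts"]])
  write_hits_table(ph$hits, paths[["hits"]])
  write_fasta(do.call(c, lapply(ph$genomes, function(g) g$contigs)),
              paths[["phages"]])
  truth <- list(ori = sim$truth$ori, ter = sim$truth$ter, h0 = sim$truth$h0,
                motif = sim$truth$motif, density = sim$truth$density,
                meth_prob = sim$truth$meth_prob,
                fst_groups = pop$truth$fst_groups,
                pi = as.list(pop$truth$pi),
                phage_clade = as.list(ph$truth$clade),
                phage_density = as.list(ph$truth$density))
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
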