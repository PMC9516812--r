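## End-to-end orchestration: simulate -> call -> profile -> compare ->
## popgen -> structure -> enrich -> viral, with a manifest recording
## every artifact, the thresholds used and their checksums.

#' Pipeline configuration
#'
#' Collects every analysis threshold in one auditable place; stage code
#' has no hidden defaults.
#'
#' @param synth a [synth_config()] describing the community.
#' @param min_coverage per-strand coverage for evaluability (default 10).
#' @param min_qv modification QV threshold (default 30).
#' @param snmv_depth per-strand depth for SNMV rows (default 20).
#' @param noise_cutoff candidate-motif methylation ratio (default 0.20).
#' @param snp_min_freq,snp_min_reads SNP rule (default > 1%, >= 4 reads).
#' @param enrich_replicates shuffle replicates (default 500).
#' @param regulatory_bp regulatory window (default 100).
#' @param skew_window,skew_step GC-skew windowing (defaults 1000/100).
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(synth = synth_config(),
                            min_coverage = 10, min_qv = 30,
                            snmv_depth = 20, noise_cutoff = 0.20,
                            snp_min_freq = 0.01, snp_min_reads = 4,
                            enrich_replicates = 500, regulatory_bp = 100,
                            skew_window = 1000, skew_step = 100) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full pipeline on a synthetic corpus
#'
#' Simulates the corpus, writes it to `out_dir`, re-reads every file
#' through the typed readers, and runs all analysis stages in
#' dependency order.  A manifest JSON lists every artifact with its
#' checksum plus the seeds and thresholds used.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return invisible list with per-stage results and the manifest path.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- simulate_corpus(config$synth, out_dir)

  g <- read_fasta(paths[["genome"]], genome_id = "synth_genome")
  genes <- read_gene_table(paths[["genes"]], dialect = "gff3")
  ipd <- utils::read.table(paths[["ipd"]], header = TRUE, sep = "\t",
                           colClasses = c(contig = "character", strand = "character",
                                          sample = "character"))
  ac <- read_allele_counts(paths[["allele_counts"]])
  hits <- read_hits_table(paths[["hits"]])

  control <- control_model(1, config$synth$sigma0)
  calls <- call_sites(ipd, control, mu_m = config$synth$mu_m,
                      min_coverage = config$min_coverage, min_qv = config$min_qv)

  spec <- motif_spec(config$synth$motif, config$synth$meth_offset,
                     config$synth$mod_type)
  sites <- scan_motif(g, spec)
  annotated <- annotate_sites(sites, calls)
  samples <- sort(unique(calls$sample))
  ratios <- vapply(samples, function(sm) {
    motif_methylation_ratio(annotated$status[annotated$sample == sm],
                            noise_cutoff = config$noise_cutoff)$ratio
  }, numeric(1))

  profiles <- do.call(rbind, lapply(samples, function(sm) {
    build_5mer_profile(g, calls[calls$sample == sm, ])
  }))
  rownames(profiles) <- samples

  snmv <- build_snmv(calls, min_depth = config$snmv_depth)
  snmv_dist <- profile_distances(t(snmv$frac), "braycurtis")
  snmv_ord <- pcoa(snmv_dist)
  intersections <- site_set_intersections(snmv$binary)

  snps <- call_snps(ac, min_freq = config$snp_min_freq,
                    min_reads = config$snp_min_reads)
  pi_by_sample <- vapply(samples, function(sm) pi_diversity(ac, sm), numeric(1))
  fst_mat <- matrix(0, length(samples), length(samples),
                    dimnames = list(samples, samples))
  for (i in seq_along(samples)[-length(samples)]) {
    for (j in (i + 1):length(samples)) {
      fst_mat[i, j] <- fst_mat[j, i] <- fst(ac, samples[i], samples[j])
    }
  }

  skew <- gc_skew(g$contigs[[1]], window = config$skew_window,
                  step = config$skew_step)
  oriter <- locate_ori_ter(skew)
  ## gradient over sites called methylated: loci the MTase never
  ## methylates carry no replication-timing signal
  site_rows <- annotated[annotated$sample == samples[1] &
                           annotated$status == "methylated", ]
  gradient <- methylation_gradient(site_rows$meth_pos, site_rows$frac, oriter,
                                   L = genome_length(g))

  partition <- classify_regions(g, genes, R = config$regulatory_bp)
  nulldist <- shuffle_null(g, genes, sites, n = config$enrich_replicates,
                           R = config$regulatory_bp, seed = config$synth$seed)
  enrich <- enrichment_test(nulldist)

  bs <- bitscore_sums(hits)
  dice <- dice_distance(bs)
  phage_tree <- neighbor_joining(dice)
  write_newick(phage_tree, file.path(out_dir, "phage_tree.nwk"))
  phages <- read_fasta(paths[["phages"]], genome_id = "phages", kingdom = "virus")
  dens <- vapply(names(phages$contigs), function(id) {
    motif_density(genome(id, phages$contigs[id], kingdom = "virus"), spec)
  }, numeric(1))
  clade <- stats::setNames(ifelse(grepl("depleted", names(dens)), "depleted", "normal"),
                           names(dens))
  clade_assoc <- clade_density_association(dens, clade)

  write_matrix(dice, file.path(out_dir, "phage_dice.csv"))
  write_matrix(snmv_dist, file.path(out_dir, "snmv_braycurtis.csv"))

  files <- c(paths, tree = file.path(out_dir, "phage_tree.nwk"),
             dice = file.path(out_dir, "phage_dice.csv"),
             snmv = file.path(out_dir, "snmv_braycurtis.csv"))
  manifest <- list(
    seed = config$synth$seed,
    thresholds = config[setdiff(names(config), "synth")],
    files = lapply(stats::setNames(as.character(files), names(files)),
                   function(f) list(path = basename(f),
                                    md5 = unname(tools::md5sum(f)))))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)

  invisible(list(
    genome = g, genes = genes, calls = calls, sites = sites,
    motif_ratios = ratios, profiles = profiles,
    snmv = snmv, snmv_ordination = snmv_ord, intersections = intersections,
    snps = snps, pi = pi_by_sample, fst = fst_mat,
    oriter = oriter, gradient = gradient,
    enrichment = enrich,
    phage = list(dice = dice, tree = phage_tree, density = dens,
                 clade = clade, association = clade_assoc),
    manifest = manifest_path))
}
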