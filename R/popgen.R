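## Population genetics from pileup allele counts: the SNP rule,
## nucleotide diversity (pi), Hudson-style F_ST, Shannon macrodiversity,
## mappability, and the methylome-vs-F_ST correlation.

ALLELE_COLS <- c("nA", "nC", "nG", "nT")

#' Call SNP loci from allele counts
#'
#' A locus is polymorphic in a sample when any non-reference allele is
#' supported by a frequency strictly above `min_freq` AND at least
#' `min_reads` reads; the SNP set is the union over samples.
#'
#' @param ac allele-counts table (see [read_allele_counts()]).
#' @param min_freq frequency threshold, strict (default 0.01).
#' @param min_reads read-support threshold, inclusive (default 4).
#' @return data.frame of loci with `is_snp` plus per-sample detail rows
#'   in `attr(, "per_sample")`.
#' @export
call_snps <- function(ac, min_freq = 0.01, min_reads = 4) {
  validate_allele_counts(ac)
  cnt <- as.matrix(ac[, ALLELE_COLS])
  depth <- rowSums(cnt)
  ref_idx <- match(paste0("n", ac$ref), ALLELE_COLS)
  alt <- cnt
  alt[cbind(seq_len(nrow(alt)), ref_idx)] <- 0L
  keep <- depth > 0
  freq <- alt / pmax(depth, 1)
  poly <- keep & apply(freq > min_freq & alt >= min_reads, 1, any)
  per_sample <- data.frame(ac[, c("contig", "position", "sample")], depth = depth,
                           polymorphic = poly)
  key <- paste(ac$contig, ac$position)
  snp <- tapply(poly, key, any)
  loci <- ac[!duplicated(key), c("contig", "position", "ref")]
  loci$is_snp <- as.logical(snp[paste(loci$contig, loci$position)])
  loci <- loci[order(loci$contig, loci$position), ]
  rownames(loci) <- NULL
  attr(loci, "per_sample") <- per_sample
  loci
}

## Per-position within-sample diversity with small-sample correction:
## pi_j = n/(n-1) * (1 - sum_a f_a^2), n = depth.
pi_per_position <- function(cnt) {
  n <- rowSums(cnt)
  f2 <- rowSums((cnt / pmax(n, 1))^2)
  ifelse(n >= 2, n / (n - 1) * (1 - f2), NA_real_)
}

#' Nucleotide diversity (pi) of one sample
#'
#' Mean over positions with depth at least `min_depth` of the corrected
#' per-position heterozygosity; monomorphic positions contribute 0.
#'
#' @param ac allele-counts table.
#' @param sample sample id.
#' @param min_depth positions below this depth are skipped (default 10).
#' @return genome-wide pi (NA when no position qualifies).
#' @export
pi_diversity <- function(ac, sample, min_depth = 10) {
  s <- ac[ac$sample == sample, , drop = FALSE]
  cnt <- as.matrix(s[, ALLELE_COLS])
  depth <- rowSums(cnt)
  use <- depth >= max(min_depth, 2)
  if (!any(use)) return(NA_real_)
  mean(pi_per_position(cnt[use, , drop = FALSE]))
}

#' Pairwise Hudson-style F_ST between two samples
#'
#' Within-sample diversities use the n/(n-1) correction; between-sample
#' diversity at a position is 1 - sum_a fX_a * fY_a (independent draws,
#' no correction).  The genome-level estimate is a ratio of averages
#' over the shared covered region:
#' F_ST = 1 - mean(piX + piY) / (2 * mean(pi_between)).
#'
#' @param ac allele-counts table.
#' @param sample_x,sample_y sample ids.
#' @param min_depth per-sample depth required at a position (default 10).
#' @return F_ST (NA when there is no between-sample diversity).
#' @export
fst <- function(ac, sample_x, sample_y, min_depth = 10) {
  if (identical(sample_x, sample_y)) return(0)
  sx <- ac[ac$sample == sample_x, , drop = FALSE]
  sy <- ac[ac$sample == sample_y, , drop = FALSE]
  key_x <- paste(sx$contig, sx$position)
  key_y <- paste(sy$contig, sy$position)
  shared <- intersect(key_x, key_y)
  sx <- sx[match(shared, key_x), , drop = FALSE]
  sy <- sy[match(shared, key_y), , drop = FALSE]
  cx <- as.matrix(sx[, ALLELE_COLS]); cy <- as.matrix(sy[, ALLELE_COLS])
  nx <- rowSums(cx); ny <- rowSums(cy)
  use <- nx >= max(min_depth, 2) & ny >= max(min_depth, 2)
  if (!any(use)) return(NA_real_)
  cx <- cx[use, , drop = FALSE]; cy <- cy[use, , drop = FALSE]
  pi_x <- pi_per_position(cx)
  pi_y <- pi_per_position(cy)
  fx <- cx / rowSums(cx); fy <- cy / rowSums(cy)
  pi_bt <- 1 - rowSums(fx * fy)
  m_bt <- mean(pi_bt)
  if (m_bt == 0) return(NA_real_)
  1 - (mean(pi_x) + mean(pi_y)) / (2 * m_bt)
}

#' F_ST computed directly from true allele frequencies
#'
#' The algebraic form of the same Hudson-style estimator on known
#' biallelic frequencies; used by the synthetic generator to record
#' ground truth.
#'
#' @param p_x,p_y vectors of alternate-allele frequencies per locus.
#' @return F_ST.
#' @export
fst_from_frequencies <- function(p_x, p_y) {
  pi_x <- 2 * p_x * (1 - p_x)
  pi_y <- 2 * p_y * (1 - p_y)
  pi_bt <- 1 - (p_x * p_y + (1 - p_x) * (1 - p_y))
  m_bt <- mean(pi_bt)
  if (m_bt == 0) return(NA_real_)
  1 - (mean(pi_x) + mean(pi_y)) / (2 * m_bt)
}

#' Shannon diversity (natural log)
#'
#' @param abundances non-negative abundance vector.
#' @return H = -sum p_i ln p_i; NA for an all-zero vector.
#' @export
shannon <- function(abundances) {
  if (any(abundances < 0)) stop("negative abundance")
  if (sum(abundances) == 0) return(NA_real_)
  as.numeric(vegan::diversity(abundances, index = "shannon"))
}

#' Percentage of subsampled reads mapped
#'
#' @param mapped_reads number of aligned reads.
#' @param subsampled_total subsample size (the study used 49 million
#'   paired reads per sample).
#' @return percentage, 100 * mapped / total.
#' @export
mappability <- function(mapped_reads, subsampled_total = 49e6) {
  stopifnot(subsampled_total > 0)
  if (any(mapped_reads > subsampled_total)) stop("mapped reads exceed total")
  100 * mapped_reads / subsampled_total
}

#' Correlate methylome dissimilarity with F_ST over sample pairs
#'
#' Pearson correlation with the usual two-sided t-based p, plus an
#' optional Mantel permutation p (the pairs of a distance matrix are not
#' independent, so the Mantel test is the honest companion).
#'
#' @param meth_dist,fst_dist distance matrices over the same samples.
#' @param permutations Mantel permutations (0 to skip; default 999).
#' @return list with `r`, `p`, `mantel_p`, `n_pairs`.
#' @export
correlate_methylome_fst <- function(meth_dist, fst_dist, permutations = 999) {
  meth_dist <- as_distance_matrix(meth_dist)
  fst_dist <- as_distance_matrix(fst_dist)
  stopifnot(identical(rownames(meth_dist), rownames(fst_dist)))
  x <- meth_dist[lower.tri(meth_dist)]
  y <- fst_dist[lower.tri(fst_dist)]
  if (length(x) < 3L) stop("need at least 3 sample pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, mantel_p = NA_real_, n_pairs = length(x)))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  mantel_p <- NA_real_
  if (permutations > 0) {
    mt <- vegan::mantel(stats::as.dist(meth_dist), stats::as.dist(fst_dist),
                        method = "pearson", permutations = permutations)
    mantel_p <- mt$signif
  }
  list(r = unname(ct$estimate), p = ct$p.value, mantel_p = mantel_p,
       n_pairs = length(x))
}
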