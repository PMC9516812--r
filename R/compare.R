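## Methylome dissimilarities, ordination and single-nucleotide
## methylation variation (SNMV).
##
## Profile vectors may contain NA where a feature had no evaluable
## occurrence; all pairwise dissimilarities here are computed over
## pairwise-complete positions only, so missingness never masquerades as
## signal.

pairwise_complete <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  list(x = x[ok], y = y[ok])
}

#' Kulczynski dissimilarity
#'
#' d = 1 - 0.5 * (sum(min(x,y))/sum(x) + sum(min(x,y))/sum(y)), computed
#' on pairwise-complete entries.  Used for 5-mer methylome profiles.
#'
#' @param x,y non-negative numeric vectors (NA allowed).
#' @return dissimilarity in \[0,1\], NA when either vector sums to zero.
#' @export
kulczynski <- function(x, y) {
  pc <- pairwise_complete(x, y)
  if (any(pc$x < 0) || any(pc$y < 0)) stop("negative profile entries")
  sx <- sum(pc$x); sy <- sum(pc$y)
  if (sx == 0 || sy == 0) return(NA_real_)
  sm <- sum(pmin(pc$x, pc$y))
  1 - 0.5 * (sm / sx + sm / sy)
}

#' Bray-Curtis dissimilarity
#'
#' d = sum(|x - y|) / sum(x + y), computed on pairwise-complete entries.
#' Used for SNMV and SNV profiles.
#'
#' @param x,y non-negative numeric vectors (NA allowed).
#' @return dissimilarity in \[0,1\], NA when both vectors are all-zero.
#' @export
bray_curtis <- function(x, y) {
  pc <- pairwise_complete(x, y)
  if (any(pc$x < 0) || any(pc$y < 0)) stop("negative profile entries")
  tot <- sum(pc$x + pc$y)
  if (tot == 0) return(NA_real_)
  sum(abs(pc$x - pc$y)) / tot
}

#' Pairwise dissimilarity matrix over profile rows
#'
#' @param profiles numeric matrix, one row per object (labelled), NA for
#'   missing features.
#' @param method `"kulczynski"` or `"braycurtis"`.
#' @return a validated distance matrix (see [as_distance_matrix()]).
#' @export
profile_distances <- function(profiles, method = c("kulczynski", "braycurtis")) {
  method <- match.arg(method)
  f <- if (method == "kulczynski") kulczynski else bray_curtis
  n <- nrow(profiles)
  if (is.null(rownames(profiles))) rownames(profiles) <- paste0("obj", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(rownames(profiles), rownames(profiles)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- f(profiles[i, ], profiles[j, ])
  }
  if (any(is.na(d))) stop("undefined dissimilarity (zero-sum profile)")
  as_distance_matrix(d)
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Double-centres -D^2/2, eigendecomposes, and returns coordinates
#' scaled by sqrt(lambda) for the positive eigenvalues.  Negative
#' eigenvalues (non-Euclidean input) are retained in the report but not
#' corrected.  Axis signs are fixed by forcing the largest-magnitude
#' loading of each axis positive.
#'
#' @param dm distance matrix (see [as_distance_matrix()]).
#' @return list with `points` (n x k coordinates), `eigenvalues` (all,
#'   descending), `prop_explained` (over positive eigenvalues).
#' @export
pcoa <- function(dm) {
  dm <- as_distance_matrix(dm)
  n <- nrow(dm)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (dm^2) %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  pos <- vals > max(vals[1], 0) * 1e-9 & vals > 0
  k <- sum(pos)
  pts <- vecs[, pos, drop = FALSE] %*% diag(sqrt(vals[pos]), k, k)
  for (j in seq_len(k)) {
    i_max <- which.max(abs(pts[, j]))
    if (pts[i_max, j] < 0) pts[, j] <- -pts[, j]
  }
  rownames(pts) <- rownames(dm)
  colnames(pts) <- if (k) paste0("PCo", seq_len(k)) else character(0)
  list(points = pts, eigenvalues = vals,
       prop_explained = if (k) vals[pos] / sum(vals[pos]) else numeric(0))
}

#' Build the SNMV matrix across samples
#'
#' Single-nucleotide methylation variation compares methylation
#' fractions site by site across samples; only position-strands with at
#' least `min_depth` coverage in every sample enter the matrix (complete
#' rows only).  The binary view applies the strict frac > 0.5 rule.
#'
#' @param calls output of [call_sites()] covering >= 2 samples.
#' @param min_depth per-strand depth required in all samples (default 20).
#' @return list with `frac` (sites x samples), `binary`, `sites`
#'   (data.frame contig, position, strand).
#' @export
build_snmv <- function(calls, min_depth = 20) {
  samples <- sort(unique(calls$sample))
  if (length(samples) < 2L) stop("SNMV requires at least 2 samples")
  key <- paste(calls$contig, calls$position, calls$strand)
  ok <- calls$coverage >= min_depth & !is.na(calls$frac)
  tab <- table(key[ok])
  common <- names(tab)[tab == length(samples)]
  if (length(common) == 0L) {
    warning("no positions covered at ", min_depth, "x in all samples")
    m <- matrix(numeric(0), 0, length(samples), dimnames = list(NULL, samples))
    return(list(frac = m, binary = m > 0.5,
                sites = data.frame(contig = character(0), position = integer(0),
                                   strand = character(0))))
  }
  common <- sort(common)
  m <- matrix(NA_real_, length(common), length(samples),
              dimnames = list(common, samples))
  for (sm in samples) {
    cs <- calls[calls$sample == sm & ok, ]
    idx <- match(common, paste(cs$contig, cs$position, cs$strand))
    m[, sm] <- cs$frac[idx]
  }
  first <- calls[match(common, key), c("contig", "position", "strand")]
  rownames(first) <- NULL
  list(frac = m, binary = m > 0.5, sites = first)
}

#' Exclusive site-set intersections across samples (UpSet semantics)
#'
#' Each site belongs to exactly one combination: the set of samples in
#' which it is methylated.  Sites methylated nowhere are reported under
#' the empty combination "".
#'
#' @param binary logical matrix sites x samples.
#' @return data.frame with columns `combination` (sample names joined by
#'   "+"), `count`, sorted by decreasing count.
#' @export
site_set_intersections <- function(binary) {
  if (is.null(colnames(binary))) colnames(binary) <- paste0("s", seq_len(ncol(binary)))
  combo <- apply(binary, 1, function(r) paste(colnames(binary)[r], collapse = "+"))
  tab <- table(combo)
  out <- data.frame(combination = names(tab), count = as.integer(tab))
  out[order(-out$count, out$combination), , drop = FALSE]
}
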