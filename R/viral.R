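## Whole-genome similarity clustering of viral genomes from pairwise
## bit-score sums: Dice distance D(A,B) = 1 - 2*AB/(AA+BB), a
## neighbor-joining tree, and the association of motif density with
## tree clades.

#' Aggregate a hits table into pairwise bit-score sums
#'
#' AB is the bit-score sum of all hits between genomes A and B; when
#' both hit directions are present they are averaged (alignment scores
#' are not symmetric).  Genomes without a self hit (AA) are dropped
#' with a warning, since their Dice distance is undefined.
#'
#' @param hits hits table (see [read_hits_table()]).
#' @return list with `genomes`, `sums` (symmetric matrix of pair sums,
#'   self sums on the diagonal).
#' @export
bitscore_sums <- function(hits) {
  if (any(hits$bit_score < 0)) stop("negative bit score")
  genomes <- sort(unique(c(hits$query, hits$subject)))
  agg <- stats::aggregate(bit_score ~ query + subject, data = hits, FUN = sum)
  m <- matrix(NA_real_, length(genomes), length(genomes),
              dimnames = list(genomes, genomes))
  m[cbind(agg$query, agg$subject)] <- agg$bit_score
  sums <- m
  for (i in seq_along(genomes)) for (j in seq_along(genomes)) {
    a <- m[i, j]; b <- m[j, i]
    sums[i, j] <- if (is.na(a) && is.na(b)) 0 else mean(c(a, b), na.rm = TRUE)
  }
  self <- diag(sums)
  keep <- !is.na(self) & self > 0
  if (!all(keep)) {
    warning("dropping genomes without a positive self bit-score sum: ",
            paste(genomes[!keep], collapse = ", "))
  }
  list(genomes = genomes[keep], sums = sums[keep, keep, drop = FALSE])
}

#' Dice distance matrix from bit-score sums
#'
#' D(A,B) = 1 - 2*AB/(AA + BB), clamped to \[0,1\]; D(A,A) = 0 exactly.
#'
#' @param bs a [bitscore_sums()] result.
#' @return validated distance matrix.
#' @export
dice_distance <- function(bs) {
  s <- bs$sums
  self <- diag(s)
  n <- nrow(s)
  d <- matrix(0, n, n, dimnames = dimnames(s))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) d[i, j] <- clamp(1 - 2 * s[i, j] / (self[i] + self[j]), 0, 1)
  }
  as_distance_matrix(d)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration.  Q-matrix ties break to the
#' lowest label-index pair; negative branch lengths are clamped to zero
#' and the total clamped deficit is recorded in
#' `attr(tree, "negative_deficit")`.
#'
#' @param dm distance matrix with at least 3 labels.
#' @return an unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  dm <- as_distance_matrix(dm)
  n <- nrow(dm)
  if (n < 3L) stop("neighbor joining needs at least 3 labels")
  labels <- rownames(dm)
  ## each active node carries its newick subtree string
  node <- labels
  d <- dm
  deficit <- 0
  clamplen <- function(v) {
    if (v < 0) { deficit <<- deficit - v; 0 } else v
  }
  while (nrow(d) > 3L) {
    r <- nrow(d)
    R <- rowSums(d)
    Q <- (r - 2) * d - outer(R, R, "+")
    diag(Q) <- Inf
    ## lowest (i, j) index pair among ties
    min_q <- min(Q)
    idx <- which(Q - min_q <= 1e-12 * max(1, abs(min_q)), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    vi <- clamplen(d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2)))
    vj <- clamplen(d[i, j] / 2 + (R[j] - R[i]) / (2 * (r - 2)))
    new_nw <- sprintf("(%s:%.12g,%s:%.12g)", node[i], vi, node[j], vj)
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d_new <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    node <- c(node[keep], new_nw)
    rownames(d_new) <- colnames(d_new) <- seq_len(nrow(d_new))
    d <- d_new
  }
  ## final three-node star: closed-form pendant lengths
  v1 <- clamplen((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  v2 <- clamplen((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  v3 <- clamplen((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  nw <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);", node[1], v1, node[2], v2, node[3], v3)
  tree <- ape::read.tree(text = nw)
  attr(tree, "negative_deficit") <- deficit
  tree
}

#' Association between motif density and tree clades
#'
#' Two-sided Wilcoxon rank-sum test of per-genome motif density between
#' two clades (e.g. GANTC density across phage groups).
#'
#' @param densities named numeric vector of motif densities per genome.
#' @param clades named character/factor vector of clade assignments
#'   over the same genomes.
#' @return list with `p`, `W`, `medians` per clade; all NA when either
#'   clade has fewer than 2 members.
#' @export
clade_density_association <- function(densities, clades) {
  common <- intersect(names(densities), names(clades))
  densities <- densities[common]; clades <- as.character(clades[common])
  lv <- unique(clades)
  if (length(lv) != 2L) stop("exactly two clades required")
  a <- densities[clades == lv[1]]; b <- densities[clades == lv[2]]
  med <- stats::setNames(c(stats::median(a), stats::median(b)), lv)
  if (length(a) < 2L || length(b) < 2L) {
    return(list(p = NA_real_, W = NA_real_, medians = med))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b))
  list(p = wt$p.value, W = unname(wt$statistic), medians = med)
}
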