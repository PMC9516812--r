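## Motif enrichment by genomic region against a coding-region shuffle
## null: densities in regulatory / genic / intergenic regions, a
## configurable number of shuffled gene placements, a Shapiro normality
## check, and z -> p conversion (empirical fallback).

## interval helpers: matrices with columns start, end (0-based half-open)
merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0L) return(matrix(numeric(0), 0, 2))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  s <- iv[, 1]; e <- iv[, 2]
  keep_s <- s[1]; keep_e <- e[1]
  for (i in seq_len(nrow(iv))[-1]) {
    if (s[i] <= keep_e[length(keep_e)]) {
      keep_e[length(keep_e)] <- max(keep_e[length(keep_e)], e[i])
    } else {
      keep_s <- c(keep_s, s[i]); keep_e <- c(keep_e, e[i])
    }
  }
  cbind(keep_s, keep_e, deparse.level = 0)
}

subtract_intervals <- function(a, b) {
  ## a minus b; both merged
  if (nrow(a) == 0L) return(a)
  if (nrow(b) == 0L) return(a)
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_len(nrow(a))) {
    s <- a[i, 1]; e <- a[i, 2]
    ov <- b[b[, 2] > s & b[, 1] < e, , drop = FALSE]
    cur <- s
    for (j in seq_len(nrow(ov))) {
      if (ov[j, 1] > cur) { out_s <- c(out_s, cur); out_e <- c(out_e, ov[j, 1]) }
      cur <- max(cur, ov[j, 2])
    }
    if (cur < e) { out_s <- c(out_s, cur); out_e <- c(out_e, e) }
  }
  cbind(out_s, out_e, deparse.level = 0)
}

interval_total <- function(iv) if (nrow(iv)) sum(iv[, 2] - iv[, 1]) else 0

in_intervals <- function(p, iv) {
  if (nrow(iv) == 0L) return(rep(FALSE, length(p)))
  idx <- findInterval(p, iv[, 1])
  idx > 0 & p < iv[pmax(idx, 1), 2]
}

#' Partition a genome into regulatory, genic and intergenic regions
#'
#' The regulatory class is a strand-aware window of `R` bp immediately
#' upstream of each gene start, truncated at contig edges; precedence is
#' genic > regulatory > intergenic, so overlaps with any gene body
#' (including neighbouring genes) resolve to genic.
#'
#' @param g a [genome()] or named vector of contig lengths.
#' @param genes gene table (0-based half-open; see [read_gene_table()]).
#' @param R regulatory window length in bp (default 100).
#' @return list of class `"region_partition"` with per-contig interval
#'   sets and total `lengths` per class.
#' @export
classify_regions <- function(g, genes, R = 100) {
  lens <- if (inherits(g, "genome")) nchar(g$contigs) else g
  validate_gene_table(genes, lens)
  contigs <- names(lens)
  per <- lapply(contigs, function(cid) {
    gg <- genes[genes$contig == cid, , drop = FALSE]
    L <- lens[[cid]]
    genic <- merge_intervals(cbind(gg$start, gg$end))
    up_s <- ifelse(gg$strand == "+", pmax(gg$start - R, 0), gg$end)
    up_e <- ifelse(gg$strand == "+", gg$start, pmin(gg$end + R, L))
    reg_raw <- cbind(up_s, up_e)[up_e > up_s, , drop = FALSE]
    regulatory <- subtract_intervals(merge_intervals(reg_raw), genic)
    list(genic = genic, regulatory = regulatory, L = L)
  })
  names(per) <- contigs
  g_len <- sum(vapply(per, function(x) interval_total(x$genic), numeric(1)))
  r_len <- sum(vapply(per, function(x) interval_total(x$regulatory), numeric(1)))
  total <- sum(lens)
  structure(list(contigs = per, R = R,
                 lengths = c(genic = g_len, regulatory = r_len,
                             intergenic = total - g_len - r_len)),
            class = "region_partition")
}

#' Classify positions against a region partition
#'
#' @param partition a [classify_regions()] result.
#' @param contig contig id(s), recycled.
#' @param position 0-based position(s).
#' @return character vector in {genic, regulatory, intergenic}.
#' @export
classify_positions <- function(partition, contig, position) {
  df <- data.frame(contig = contig, position = position)
  out <- character(nrow(df))
  for (cid in unique(df$contig)) {
    sel <- df$contig == cid
    p <- df$position[sel]
    iv <- partition$contigs[[cid]]
    if (is.null(iv)) stop("unknown contig: ", cid)
    cls <- rep("intergenic", length(p))
    cls[in_intervals(p, iv$regulatory)] <- "regulatory"
    cls[in_intervals(p, iv$genic)] <- "genic"
    out[sel] <- cls
  }
  out
}

#' Motif density per genomic region
#'
#' A site's region is determined by its methylated-base coordinate.
#'
#' @param sites [scan_motif()] output (columns contig, meth_pos).
#' @param partition a [classify_regions()] result.
#' @return data.frame with region, count, length_bp, density (sites/kb;
#'   NA for an empty region).
#' @export
region_density <- function(sites, partition) {
  cls <- classify_positions(partition, sites$contig, sites$meth_pos)
  regions <- c("regulatory", "genic", "intergenic")
  count <- vapply(regions, function(r) sum(cls == r), numeric(1))
  len <- partition$lengths[regions]
  data.frame(region = regions, count = as.integer(count),
             length_bp = as.numeric(len),
             density = ifelse(len > 0, count * 1000 / len, NA_real_),
             row.names = NULL)
}

## Uniform placement of n non-overlapping intervals of length `len` on
## [0, L): draw n sorted uniform starts on the compacted line and add
## back the cumulative gene lengths.
place_genes_uniform <- function(n, len, L) {
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  slack <- L - n * len
  if (slack < 0) stop("infeasible gene placement: total gene length exceeds contig")
  starts <- sort(stats::runif(n, 0, slack)) + (seq_len(n) - 1) * len
  starts <- floor(starts)
  cbind(starts, starts + len, deparse.level = 0)
}

#' Coding-region shuffle null for motif region densities
#'
#' Each replicate replaces the annotated genes with randomly placed
#' non-overlapping genes -- the observed number of genes per strand per
#' contig, each at the observed mean gene length -- recomputes the
#' region partition, and records the three region densities for the
#' fixed motif sites.
#'
#' @param g a [genome()].
#' @param genes observed gene table.
#' @param sites [scan_motif()] output for the motif under test.
#' @param n number of replicates (default 500).
#' @param R regulatory window length (default 100).
#' @param seed integer seed for reproducible placements.
#' @return list of class `"null_distribution"`: `observed` (named
#'   density vector), `null` (n x 3 matrix), `shapiro_p` per region,
#'   `n`, `R`.
#' @export
shuffle_null <- function(g, genes, sites, n = 500, R = 100, seed = 1) {
  set.seed(substream_seed(seed, "shuffle_null"))
  obs_part <- classify_regions(g, genes, R)
  obs <- region_density(sites, obs_part)
  obs_d <- stats::setNames(obs$density, obs$region)
  lens <- nchar(g$contigs)
  ## observed per-contig per-strand gene statistics
  stats_tab <- lapply(names(lens), function(cid) {
    gg <- genes[genes$contig == cid, , drop = FALSE]
    lapply(c("+", "-"), function(st) {
      sel <- gg$strand == st
      list(n = sum(sel),
           len = if (any(sel)) round(mean(gg$end[sel] - gg$start[sel])) else 0)
    })
  })
  names(stats_tab) <- names(lens)
  null <- matrix(NA_real_, n, 3,
                 dimnames = list(NULL, c("regulatory", "genic", "intergenic")))
  site_pos <- split(sites$meth_pos, sites$contig)
  total_len <- sum(lens)
  for (r in seq_len(n)) {
    counts <- c(regulatory = 0, genic = 0, intergenic = 0)
    len_gr <- c(genic = 0, regulatory = 0)
    for (cid in names(lens)) {
      L <- lens[[cid]]
      iv_p <- place_genes_uniform(stats_tab[[cid]][[1]]$n,
                                  stats_tab[[cid]][[1]]$len, L)
      iv_m <- place_genes_uniform(stats_tab[[cid]][[2]]$n,
                                  stats_tab[[cid]][[2]]$len, L)
      genic <- merge_intervals(rbind(iv_p, iv_m))
      reg_raw <- rbind(
        if (nrow(iv_p)) cbind(pmax(iv_p[, 1] - R, 0), iv_p[, 1]),
        if (nrow(iv_m)) cbind(iv_m[, 2], pmin(iv_m[, 2] + R, L)))
      reg_raw <- reg_raw[reg_raw[, 2] > reg_raw[, 1], , drop = FALSE]
      regulatory <- subtract_intervals(merge_intervals(reg_raw), genic)
      len_gr["genic"] <- len_gr["genic"] + interval_total(genic)
      len_gr["regulatory"] <- len_gr["regulatory"] + interval_total(regulatory)
      p <- site_pos[[cid]]
      if (!is.null(p) && length(p)) {
        g_hit <- in_intervals(p, genic)
        r_hit <- !g_hit & in_intervals(p, regulatory)
        counts["genic"] <- counts["genic"] + sum(g_hit)
        counts["regulatory"] <- counts["regulatory"] + sum(r_hit)
        counts["intergenic"] <- counts["intergenic"] + sum(!g_hit & !r_hit)
      }
    }
    lens3 <- c(regulatory = unname(len_gr["regulatory"]),
               genic = unname(len_gr["genic"]),
               intergenic = total_len - sum(len_gr))
    null[r, ] <- ifelse(lens3 > 0, counts[colnames(null)] * 1000 / lens3, NA_real_)
  }
  shapiro_p <- apply(null, 2, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 3L || stats::sd(v) == 0) return(NA_real_)
    stats::shapiro.test(if (length(v) > 5000) v[seq_len(5000)] else v)$p.value
  })
  structure(list(observed = obs_d, null = null, shapiro_p = shapiro_p,
                 n = n, R = R), class = "null_distribution")
}

#' Enrichment test from a shuffle null
#'
#' Per region: when the null passes the Shapiro normality check
#' (p > 0.05), z = (obs - mean)/sd with a two-sided normal p; otherwise
#' (or when sd = 0) a two-sided empirical p,
#' (1 + #\{|null - mean| >= |obs - mean|\}) / (n + 1).
#'
#' @param nd a [shuffle_null()] result with at least 100 replicates.
#' @return data.frame per region: observed, null_mean, null_sd,
#'   shapiro_p, z, p, method.
#' @export
enrichment_test <- function(nd) {
  stopifnot(inherits(nd, "null_distribution"))
  if (nd$n < 100L) stop("need at least 100 null replicates")
  do.call(rbind, lapply(colnames(nd$null), function(rg) {
    v <- nd$null[, rg]
    obs <- nd$observed[[rg]]
    m <- mean(v); s <- stats::sd(v)
    sp <- nd$shapiro_p[[rg]]
    if (!is.na(sp) && sp > 0.05 && s > 0) {
      z <- (obs - m) / s
      p <- 2 * stats::pnorm(-abs(z))
      method <- "z"
    } else {
      z <- NA_real_
      p <- (1 + sum(abs(v - m) >= abs(obs - m))) / (nd$n + 1)
      method <- "empirical"
    }
    data.frame(region = rg, observed = obs, null_mean = m, null_sd = s,
               shapiro_p = sp, z = z, p = p, method = method, row.names = NULL)
  }))
}
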