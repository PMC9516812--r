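## IUPAC motif scanning and motif/5-mer methylome profiles.
##
## Motif matches are reported per strand in plus-strand coordinates: a
## minus-strand site at start s means the reverse complement of the motif
## matches the plus strand at s, i.e. the motif matches the minus strand
## there.  N in the genome never matches any motif symbol.

#' Motif specification
#'
#' @param iupac motif string over the IUPAC alphabet.
#' @param meth_offset 0-based index of the methylated base within the
#'   motif (reading the motif 5'->3' on its own strand).
#' @param mod_type `"m6A"`, `"m4C"` or `"unknown"`.
#' @return list of class `"motif_spec"`.
#' @export
motif_spec <- function(iupac, meth_offset, mod_type = "m6A") {
  iupac <- toupper(iupac)
  if (!is_valid_iupac(iupac)) stop("invalid IUPAC motif: ", iupac)
  if (meth_offset < 0 || meth_offset >= nchar(iupac)) {
    stop("meth_offset must lie within the motif")
  }
  structure(list(iupac = iupac, meth_offset = as.integer(meth_offset),
                 mod_type = mod_type), class = "motif_spec")
}

regex_matches <- function(seq, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L  # 0-based starts
}

#' Scan a genome for an IUPAC motif on both strands
#'
#' Overlapping matches are all reported and strands are counted
#' separately, so a self-complementary motif such as GANTC yields two
#' sites per genomic locus.
#'
#' @param g a [genome()] (or named character vector of sequences).
#' @param motif a [motif_spec()] or plain IUPAC string (then
#'   `meth_offset` 0 is assumed).
#' @return data.frame with columns contig, start (0-based, plus-strand
#'   coordinate of the leftmost matched base), strand, motif, meth_pos
#'   (plus-strand coordinate of the methylated base).
#' @export
scan_motif <- function(g, motif) {
  if (is.character(motif)) motif <- motif_spec(motif, 0L)
  contigs <- if (inherits(g, "genome")) g$contigs else g
  k <- nchar(motif$iupac)
  fwd <- iupac_to_regex(motif$iupac)
  rev_ <- iupac_to_regex(revcomp(motif$iupac))
  out <- lapply(names(contigs), function(cid) {
    s <- contigs[[cid]]
    pf <- regex_matches(s, fwd)
    pr <- regex_matches(s, rev_)
    rbind(
      if (length(pf)) data.frame(contig = cid, start = pf, strand = "+"),
      if (length(pr)) data.frame(contig = cid, start = pr, strand = "-")
    )
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L) {
    return(data.frame(contig = character(0), start = integer(0),
                      strand = character(0), motif = character(0),
                      meth_pos = integer(0)))
  }
  out$motif <- motif$iupac
  out$meth_pos <- ifelse(out$strand == "+", out$start + motif$meth_offset,
                         out$start + k - 1L - motif$meth_offset)
  out[order(out$contig, out$start, out$strand), , drop = FALSE]
}

#' Annotate motif sites with per-sample methylation status
#'
#' Joins motif sites to site-level calls by the methylated-base
#' coordinate and strand; sites with no call are unevaluable.
#'
#' @param sites output of [scan_motif()].
#' @param calls output of [call_sites()] for one or more samples.
#' @return data.frame of sites x samples with status and frac.
#' @export
annotate_sites <- function(sites, calls) {
  samples <- unique(calls$sample)
  out <- do.call(rbind, lapply(samples, function(sm) {
    cs <- calls[calls$sample == sm, ]
    idx <- match(paste(sites$contig, sites$meth_pos, sites$strand),
                 paste(cs$contig, cs$position, cs$strand))
    data.frame(sites, sample = sm,
               status = ifelse(is.na(idx), "unevaluable", cs$status[idx]),
               frac = ifelse(is.na(idx), NA_real_, cs$frac[idx]))
  }))
  rownames(out) <- NULL
  out
}

#' Motif methylation ratio for one genome-sample pair
#'
#' Ratio of methylated to evaluable motif sites; unevaluable sites never
#' enter the denominator.  Following the noise rule, a motif is flagged
#' as a candidate methylation motif when at least 20% of its evaluable
#' sites are methylated.
#'
#' @param status character vector of per-site status values
#'   (`methylated` / `unmethylated` / `unevaluable`).
#' @param noise_cutoff candidate threshold (default 0.20).
#' @return list with `ratio` (NA when no site is evaluable), `n_meth`,
#'   `n_eval`, `candidate`.
#' @export
motif_methylation_ratio <- function(status, noise_cutoff = 0.20) {
  n_meth <- sum(status == "methylated")
  n_eval <- n_meth + sum(status == "unmethylated")
  ratio <- if (n_eval == 0L) NA_real_ else n_meth / n_eval
  list(ratio = ratio, n_meth = n_meth, n_eval = n_eval,
       candidate = !is.na(ratio) && ratio >= noise_cutoff)
}

#' Kingdom-specific breadth filter
#'
#' Genome-sample pairs whose 10x breadth of coverage falls below the
#' kingdom threshold are excluded from methylome profiling: prokaryotes
#' and giant viruses 20%, eukaryotes 10%, viruses 60%.  The drop is a
#' strict less-than, so a breadth exactly at the threshold is kept.
#'
#' @param breadth_10x fraction of genome positions with depth >= 10.
#' @param kingdom genome kingdom.
#' @return TRUE to keep the pair.
#' @export
breadth_filter <- function(breadth_10x, kingdom) {
  thr <- c(prokaryote = 0.20, eukaryote = 0.10, virus = 0.60, giant_virus = 0.20)
  if (!kingdom %in% names(thr)) stop("unknown kingdom: ", kingdom)
  breadth_10x >= thr[[kingdom]]
}

#' 5-mer methylome profile
#'
#' For every 5-mer context w (1024 in total), the fraction of its
#' occurrences whose centre base is called methylated, among occurrences
#' whose centre base is evaluable.  Both strands contribute: the
#' minus-strand occurrence of a window is the reverse complement of the
#' plus-strand window, and the centre base status is taken on the
#' corresponding strand.  5-mers with no evaluable occurrence are NA,
#' not zero.
#'
#' @param g a [genome()].
#' @param calls output of [call_sites()] restricted to one sample.
#' @return named numeric vector over the 1024 5-mers.
#' @export
build_5mer_profile <- function(g, calls) {
  kmers <- sort(do.call(paste0, expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                            c("A","C","G","T"), c("A","C","G","T"),
                                            c("A","C","G","T"), stringsAsFactors = FALSE)))
  meth <- stats::setNames(numeric(1024), kmers)
  evaln <- stats::setNames(numeric(1024), kmers)
  ev <- calls[calls$status != "unevaluable", , drop = FALSE]
  if (nrow(ev)) {
    for (cid in unique(ev$contig)) {
      s <- g$contigs[[cid]]
      L <- nchar(s)
      rows <- ev[ev$contig == cid, ]
      ok <- rows$position >= 2 & rows$position <= L - 3
      rows <- rows[ok, ]
      if (!nrow(rows)) next
      win <- substring(s, rows$position - 1, rows$position + 3)
      win <- ifelse(rows$strand == "-", revcomp(win), win)
      keep <- !grepl("N", win, fixed = TRUE)
      rows <- rows[keep, ]; win <- win[keep]
      if (!nrow(rows)) next
      tab_eval <- table(win)
      evaln[names(tab_eval)] <- evaln[names(tab_eval)] + as.numeric(tab_eval)
      mwin <- win[rows$status == "methylated"]
      if (length(mwin)) {
        tab_m <- table(mwin)
        meth[names(tab_m)] <- meth[names(tab_m)] + as.numeric(tab_m)
      }
    }
  }
  out <- meth / evaln
  out[evaln == 0] <- NA_real_
  out
}

#' Pair the two strand-sites of a palindromic motif locus
#'
#' For a self-complementary motif every genomic locus carries one site
#' per strand; their joint status distinguishes full methylation (both
#' strands), hemimethylation (one strand methylated, the other
#' unmethylated), unmethylated, and unevaluable loci (either strand
#' unevaluable without an unambiguous hemi call).
#'
#' @param annotated output of [annotate_sites()] for a single sample and
#'   a self-complementary motif.
#' @return data.frame with contig, start, state per locus.
#' @export
pair_palindromic_sites <- function(annotated) {
  motif <- unique(annotated$motif)
  stopifnot(length(motif) == 1L)
  if (!is_palindromic_motif(motif)) {
    stop("motif ", motif, " is not self-complementary")
  }
  key <- paste(annotated$contig, annotated$start)
  out <- do.call(rbind, lapply(split(annotated, key), function(d) {
    st <- d$status
    state <- if (sum(st == "methylated") == 2L) "full"
    else if (sum(st == "methylated") == 1L && sum(st == "unmethylated") == 1L) "hemi"
    else if (all(st == "unmethylated") && nrow(d) == 2L) "unmethylated"
    else "unevaluable"
    data.frame(contig = d$contig[1], start = d$start[1], state = state)
  }))
  rownames(out) <- NULL
  out[order(out$contig, out$start), , drop = FALSE]
}

#' Motif density in sites per kilobase
#'
#' Both-strand site count scaled by total genome length.
#'
#' @param g a [genome()] or total length in bp.
#' @param motif a [motif_spec()] or IUPAC string.
#' @param sites optional pre-computed [scan_motif()] output.
#' @return sites per kb.
#' @export
motif_density <- function(g, motif, sites = NULL) {
  if (is.null(sites)) sites <- scan_motif(g, motif)
  L <- if (inherits(g, "genome")) genome_length(g) else sum(nchar(g))
  nrow(sites) * 1000 / L
}

## Probability that a random order-1 Markov word matches an IUPAC motif,
## via a forward pass over the degenerate positions.
markov_motif_prob <- function(motif, init, trans) {
  ch <- strsplit(toupper(motif), "", fixed = TRUE)[[1]]
  sets <- lapply(ch, function(s) strsplit(IUPAC_MAP[[s]], "")[[1]])
  # v[b] = prob of emitting a word so far ending in base b and matching
  v <- stats::setNames(numeric(4), c("A", "C", "G", "T"))
  v[sets[[1]]] <- init[sets[[1]]]
  for (i in seq_along(sets)[-1]) {
    w <- stats::setNames(numeric(4), c("A", "C", "G", "T"))
    for (b in sets[[i]]) w[b] <- sum(v * trans[, b])
    v <- w
  }
  sum(v)
}

#' Observed/expected motif depletion score
#'
#' Expected both-strand motif count under an order-1 Markov model fitted
#' to the genome itself; scores below 1 indicate motif avoidance
#' (depletion), as seen for restriction-site motifs in phage genomes.
#'
#' @param g a [genome()].
#' @param motif a [motif_spec()] or IUPAC string.
#' @return list with `observed`, `expected`, `score`.
#' @export
depletion_score <- function(g, motif) {
  if (is.character(motif)) motif <- motif_spec(motif, 0L)
  k <- nchar(motif$iupac)
  if (genome_length(g) < k) stop("genome shorter than motif")
  bases <- c("A", "C", "G", "T")
  trans <- matrix(0, 4, 4, dimnames = list(bases, bases))
  init <- stats::setNames(numeric(4), bases)
  npos <- 0
  for (s in g$contigs) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    keep <- ch %in% bases
    init_t <- table(factor(ch[keep], levels = bases))
    init <- init + as.numeric(init_t)
    pair_ok <- keep[-length(ch)] & keep[-1]
    if (any(pair_ok)) {
      t2 <- table(factor(ch[-length(ch)][pair_ok], levels = bases),
                  factor(ch[-1][pair_ok], levels = bases))
      trans <- trans + as.matrix(t2)
    }
    npos <- npos + sum(keep) - k + 1
  }
  init <- init / sum(init)
  trans <- trans / pmax(rowSums(trans), 1)
  p <- markov_motif_prob(motif$iupac, init, trans) +
    markov_motif_prob(revcomp(motif$iupac), init, trans)
  expected <- npos * p
  observed <- nrow(scan_motif(g, motif))
  list(observed = observed, expected = expected,
       score = if (expected > 0) observed / expected else NA_real_)
}

## Build a degenerate IUPAC consensus from aligned k-mers (one symbol per
## column covering the bases that account for >= min_base_frac of sites).
consensus_iupac <- function(kmers, weights, min_base_frac = 0.1) {
  k <- nchar(kmers[1])
  mat <- do.call(rbind, strsplit(kmers, "", fixed = TRUE))
  code_of <- stats::setNames(names(IUPAC_MAP), vapply(IUPAC_MAP, function(b)
    paste(sort(strsplit(b, "")[[1]]), collapse = ""), character(1)))
  paste(vapply(seq_len(k), function(i) {
    w <- tapply(weights, factor(mat[, i], levels = c("A", "C", "G", "T")), sum)
    w[is.na(w)] <- 0
    bases <- names(w)[w / sum(w) >= min_base_frac]
    code_of[[paste(sort(bases), collapse = "")]]
  }, character(1)), collapse = "")
}

#' Discover context motifs around methylated positions
#'
#' Extracts strand-aware k-mer windows centred on methylated positions,
#' tests each distinct k-mer for enrichment over its genome background
#' frequency (one-sided binomial, BH-corrected), and collapses the
#' significant k-mers into a degenerate consensus with flanking N
#' positions trimmed.
#'
#' @param g a [genome()].
#' @param calls output of [call_sites()] for one sample.
#' @param k window width (odd, default 7).
#' @param alpha BH-adjusted significance cutoff (default 0.01).
#' @param min_sites minimum number of methylated positions (default 50).
#' @param min_count minimum window support per candidate k-mer (default
#'   3); chance k-mer collisions between a pair of random windows carry
#'   no motif structure, so k-mers below this support are never tested.
#' @return data.frame of candidate k-mers (kmer, count, expected, p_adj)
#'   with the collapsed consensus in `attr(, "consensus")`; zero rows
#'   (with a warning) when input is insufficient or nothing is enriched.
#' @export
discover_context_motifs <- function(g, calls, k = 7, alpha = 0.01, min_sites = 50,
                                    min_count = NULL) {
  stopifnot(k %% 2 == 1)
  half <- (k - 1) / 2
  mcalls <- calls[calls$status == "methylated", , drop = FALSE]
  empty <- data.frame(kmer = character(0), count = integer(0),
                      expected = numeric(0), p_adj = numeric(0))
  attr(empty, "consensus") <- NA_character_
  if (nrow(mcalls) < min_sites) {
    warning("too few methylated positions (", nrow(mcalls), " < ", min_sites, ")")
    return(empty)
  }
  win <- character(0)
  for (cid in unique(mcalls$contig)) {
    s <- g$contigs[[cid]]
    rows <- mcalls[mcalls$contig == cid, ]
    ok <- rows$position >= half & rows$position <= nchar(s) - half - 1
    rows <- rows[ok, ]
    if (!nrow(rows)) next
    w <- substring(s, rows$position - half + 1, rows$position + half + 1)
    w <- ifelse(rows$strand == "-", revcomp(w), w)
    win <- c(win, w[!grepl("N", w, fixed = TRUE)])
  }
  if (length(win) < min_sites) {
    warning("too few usable methylated windows")
    return(empty)
  }
  ## genome background frequency of each candidate k-mer (both strands)
  if (is.null(min_count)) min_count <- 3L
  cnt <- table(win)
  cnt <- cnt[cnt >= min_count]
  if (length(cnt) == 0L) {
    attr(empty, "consensus") <- NA_character_
    return(empty)
  }
  L2 <- 2 * sum(pmax(nchar(g$contigs) - k + 1, 0))
  bg <- vapply(names(cnt), function(w) {
    obs <- sum(vapply(g$contigs, function(s) {
      length(regex_matches(s, w)) + length(regex_matches(s, revcomp(w)))
    }, numeric(1)))
    max(obs, 1) / L2
  }, numeric(1))
  n <- length(win)
  p <- vapply(seq_along(cnt), function(i) {
    stats::pbinom(as.numeric(cnt[i]) - 1, n, bg[i], lower.tail = FALSE)
  }, numeric(1))
  ## correct over the full k-mer hypothesis space, not just the k-mers
  ## that happened to be observed (guards against birthday collisions)
  p_adj <- pmin(p * 4^k, 1)
  keep <- p_adj < alpha
  res <- data.frame(kmer = names(cnt)[keep], count = as.integer(cnt[keep]),
                    expected = n * bg[keep], p_adj = p_adj[keep])
  res <- res[order(res$p_adj, -res$count, res$kmer), , drop = FALSE]
  rownames(res) <- NULL
  if (nrow(res) == 0L) {
    attr(res, "consensus") <- NA_character_
    return(res)
  }
  ## once any k-mer is significantly enriched, derive the degenerate
  ## consensus from the full window set (robust to count dilution over
  ## degenerate positions), trimming uninformative flanks
  cons <- consensus_iupac(win, rep(1, length(win)))
  cons <- sub("^N+", "", sub("N+$", "", cons))
  attr(res, "consensus") <- cons
  res
}
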