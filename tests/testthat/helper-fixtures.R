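# Shared fixture builders; everything is generated in code.

random_dna <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# brute-force IUPAC scan oracle: position-by-position base-set membership
# on both strands, independent of the regex implementation
oracle_scan <- function(seqs, motif_str) {
  map <- c(A = "A", C = "C", G = "G", T = "T",
           R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
           B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  rc <- function(m) paste(rev(comp[strsplit(m, "")[[1]]]), collapse = "")
  match_at <- function(ch, pat, pos) {
    pch <- strsplit(pat, "")[[1]]
    all(vapply(seq_along(pch), function(i) {
      b <- ch[pos + i - 1]
      b %in% strsplit(map[[pch[i]]], "")[[1]]  # N in genome matches nothing
    }, logical(1)))
  }
  out <- NULL
  for (cid in names(seqs)) {
    ch <- strsplit(seqs[[cid]], "")[[1]]
    k <- nchar(motif_str)
    for (pos in seq_len(length(ch) - k + 1)) {
      if (match_at(ch, motif_str, pos)) {
        out <- rbind(out, data.frame(contig = cid, start = pos - 1L, strand = "+"))
      }
      if (match_at(ch, rc(motif_str), pos)) {
        out <- rbind(out, data.frame(contig = cid, start = pos - 1L, strand = "-"))
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(contig = character(0), start = integer(0), strand = character(0))
  }
  out[order(out$contig, out$start, out$strand), , drop = FALSE]
}

# molecule-level IPD draws for a single site with true fraction f
draw_site_ipd <- function(n, f, mu_m = 4, sigma = 0.35) {
  nm <- rbinom(1, n, f)
  c(rlnorm(nm, log(mu_m) - sigma^2 / 2, sigma),
    rlnorm(n - nm, log(1) - sigma^2 / 2, sigma))
}

# minimal calls table row builder
make_calls <- function(contig, position, strand, sample, status,
                       frac = NA_real_, coverage = 50, qv = 60) {
  n <- length(position)
  data.frame(contig = rep_len(contig, n), position = position,
             strand = rep_len(strand, n), sample = rep_len(sample, n),
             coverage = rep_len(coverage, n), t = rep_len(NA_real_, n),
             p = rep_len(NA_real_, n),
             qv = rep_len(qv, n), frac = rep_len(frac, n),
             status = rep_len(status, n))
}

small_config <- function(seed = 1, ...) {
  args <- list(seed = seed, genome_length = 12000, genes_per_strand = 6,
               gene_mean_length = 600, n_samples = 2, depth_mean = 50,
               n_loci = 200, n_background = 40)
  args <- utils::modifyList(args, list(...))
  do.call(synth_config, args)
}
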