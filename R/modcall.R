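## Per-site modification detection from per-molecule IPD ratios.
##
## The kinetic signal of m6A/m4C is an elevated interpulse-duration (IPD)
## ratio relative to an unmodified control.  Each genomic position-strand
## is tested with a one-sample upper-tail t test of its molecule-level IPD
## ratios against the control mean; the modification QV is -10*log10(p).
## Because a position pools molecules from many cells, the mean IPD ratio
## also carries the fraction of cells methylated at that site, estimated
## by method of moments.

QV_CAP <- 1000

#' Control kinetic model
#'
#' @param mu0 expected IPD ratio for an unmodified base (default 1).
#' @param sigma0 control standard deviation (> 0).
#' @return list with class `"control_model"`.
#' @export
control_model <- function(mu0 = 1, sigma0 = 0.35) {
  stopifnot(sigma0 > 0)
  structure(list(mu0 = mu0, sigma0 = sigma0), class = "control_model")
}

#' Test one position for modification
#'
#' One-sample, one-sided (upper) t test of the mean IPD ratio against the
#' control mean.  Degenerate zero-variance inputs are handled
#' deterministically: if the common value equals the control mean the
#' position is called unmodified (p = 1); if it exceeds the control mean
#' with at least 10 molecules, p underflows and QV hits the cap.
#'
#' @param ipd_ratios numeric vector of per-molecule IPD ratios.
#' @param control a [control_model()].
#' @return list with `n`, `t`, `p`, `qv`, `mean_ipd`; all NA (with
#'   `callable = FALSE`) when fewer than 2 observations are available.
#' @export
detect_modified_position <- function(ipd_ratios, control = control_model()) {
  ipd_ratios <- ipd_ratios[is.finite(ipd_ratios)]
  n <- length(ipd_ratios)
  if (n < 2L) {
    return(list(n = n, t = NA_real_, p = NA_real_, qv = NA_real_,
                mean_ipd = if (n) mean(ipd_ratios) else NA_real_, callable = FALSE))
  }
  m <- mean(ipd_ratios)
  s <- stats::sd(ipd_ratios)
  if (s == 0) {
    if (m > control$mu0 && n >= 10L) {
      p <- 0
    } else {
      p <- 1
    }
    tstat <- if (m > control$mu0) Inf else 0
  } else {
    tstat <- (m - control$mu0) / (s / sqrt(n))
    p <- stats::pt(tstat, df = n - 1, lower.tail = FALSE)
  }
  qv <- if (p <= 0) QV_CAP else min(-10 * log10(p), QV_CAP)
  list(n = n, t = tstat, p = p, qv = qv, mean_ipd = m, callable = TRUE)
}

#' Estimate the methylated cell fraction at a position
#'
#' Method-of-moments estimate under a two-component mixture: unmodified
#' molecules have mean IPD ratio `mu0`, fully modified molecules `mu_m`,
#' so a pooled mean m gives f = (m - mu0) / (mu_m - mu0), clipped to
#' \[0,1\].
#'
#' @param ipd_ratios numeric vector of per-molecule IPD ratios (or a
#'   single pre-computed mean).
#' @param control a [control_model()].
#' @param mu_m expected IPD ratio of a fully modified base; must exceed
#'   `mu0`.
#' @return fraction in \[0,1\].
#' @export
estimate_fraction <- function(ipd_ratios, control = control_model(), mu_m = 4) {
  if (mu_m <= control$mu0) stop("mu_m must exceed mu0 (no kinetic signal)")
  m <- mean(ipd_ratios)
  clamp((m - control$mu0) / (mu_m - control$mu0), 0, 1)
}

#' Call modification status genome-wide
#'
#' Applies [detect_modified_position()] and [estimate_fraction()] per
#' (contig, position, strand, sample) group of an IPD observation table
#' and classifies each site with the coverage/QV criteria: a site needs
#' at least `min_coverage` molecules on its strand to be evaluable at
#' all, and is called methylated when its QV reaches `min_qv`.
#' Unevaluable is a distinct status from unmethylated throughout the
#' pipeline.
#'
#' @param ipd data.frame with columns contig, position, strand, sample,
#'   ipd_ratio (one row per molecule observation).
#' @param control a [control_model()].
#' @param mu_m modified-base mean IPD ratio used for fraction estimation.
#' @param min_coverage minimum per-strand coverage (default 10).
#' @param min_qv minimum modification QV (default 30).
#' @return data.frame with one row per site-sample: contig, position,
#'   strand, sample, coverage, t, p, qv, frac, status in
#'   {methylated, unmethylated, unevaluable}.
#' @export
call_sites <- function(ipd, control = control_model(), mu_m = 4,
                       min_coverage = 10, min_qv = 30) {
  need <- c("contig", "position", "strand", "sample", "ipd_ratio")
  if (!all(need %in% names(ipd))) stop("ipd table must have columns ", paste(need, collapse = ", "))
  key <- interaction(ipd$contig, ipd$position, ipd$strand, ipd$sample, drop = TRUE)
  groups <- split(ipd$ipd_ratio, key)
  meta <- ipd[!duplicated(key), c("contig", "position", "strand", "sample")]
  meta <- meta[match(levels(key), key[!duplicated(key)]), ]
  res <- lapply(groups, function(v) {
    d <- detect_modified_position(v, control)
    frac <- if (d$n >= 2L) estimate_fraction(v, control, mu_m) else NA_real_
    c(n = d$n, t = d$t, p = d$p, qv = d$qv, frac = frac)
  })
  rm <- do.call(rbind, res)
  out <- data.frame(meta, coverage = as.integer(rm[, "n"]),
                    t = rm[, "t"], p = rm[, "p"], qv = rm[, "qv"],
                    frac = rm[, "frac"], row.names = NULL)
  out$status <- site_status(out$coverage, out$qv, min_coverage, min_qv)
  out$frac[out$status == "unevaluable"] <- NA_real_
  out[order(out$contig, out$position, out$strand, out$sample), , drop = FALSE]
}

#' Three-valued site status from the coverage/QV criteria
#'
#' Sites below `min_coverage` on their strand are unevaluable (distinct
#' from unmethylated); evaluable sites are methylated when the QV
#' reaches `min_qv` (inclusive).
#'
#' @param coverage per-strand molecule count.
#' @param qv modification QV (NA treated as failing).
#' @param min_coverage coverage threshold, inclusive (default 10).
#' @param min_qv QV threshold, inclusive (default 30).
#' @return character vector in {methylated, unmethylated, unevaluable}.
#' @export
site_status <- function(coverage, qv, min_coverage = 10, min_qv = 30) {
  ifelse(coverage < min_coverage, "unevaluable",
         ifelse(!is.na(qv) & qv >= min_qv, "methylated", "unmethylated"))
}

#' Convert calls to modification records
#'
#' @param calls output of [call_sites()], optionally filtered.
#' @param mod_type modification type tag for the records.
#' @return modification-record data.frame (see [read_modifications()]).
#' @export
calls_to_modifications <- function(calls, mod_type = "m6A") {
  validate_modifications(data.frame(
    contig = calls$contig, position = calls$position, strand = calls$strand,
    mod_type = mod_type, coverage = calls$coverage,
    qv = ifelse(is.na(calls$qv), 0, calls$qv), frac = calls$frac))
}
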