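## Replication-structure analysis: GC skew, ori/ter localisation, and
## the cell-cycle methylation gradient.
##
## In many bacteria the leading strand carries a G excess, so the GC
## skew (G-C)/(G+C) changes sign at the replication origin and terminus
## and the cumulative skew attains its minimum at ori and maximum at
## ter.  CcrM-type methylation lags the replication fork: positions near
## ori spend longer hemimethylated in a growing population, which lowers
## their pooled methylation fraction relative to ter.

#' Windowed GC skew
#'
#' @param sequence DNA string (single replicon; concatenate contigs in a
#'   known order beforehand).
#' @param window window size in bp (default 1000).
#' @param step step between window starts in bp (default 100).
#' @return list of class `"skew_profile"` with `starts` (0-based window
#'   starts), `skew`, `cumulative`, `window`, `step`, `length`.
#' @export
gc_skew <- function(sequence, window = 1000, step = 100) {
  L <- nchar(sequence)
  if (window > L) stop("window larger than sequence")
  starts <- seq(0L, L - window, by = step)
  ch <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  isG <- cumsum(c(0L, ch == "G"))
  isC <- cumsum(c(0L, ch == "C"))
  g <- isG[starts + window + 1L] - isG[starts + 1L]
  cc <- isC[starts + window + 1L] - isC[starts + 1L]
  skew <- ifelse(g + cc == 0, 0, (g - cc) / (g + cc))
  structure(list(starts = starts, skew = skew, cumulative = cumsum(skew),
                 window = window, step = step, length = L),
            class = "skew_profile")
}

#' Locate replication origin and terminus from cumulative GC skew
#'
#' ori is the window centre at the cumulative-skew global minimum and
#' ter at the global maximum (leading-strand G-excess convention); ties
#' break to the lowest coordinate.
#'
#' @param profile a [gc_skew()] profile with at least 10 windows.
#' @param circular logical, recorded in the result.
#' @return list of class `"ori_ter"` with `ori`, `ter`, `circular`,
#'   `length`; NA positions (with a warning) for a flat profile.
#' @export
locate_ori_ter <- function(profile, circular = TRUE) {
  stopifnot(inherits(profile, "skew_profile"))
  if (length(profile$starts) < 10L) stop("need at least 10 windows")
  cs <- profile$cumulative
  if (max(cs) - min(cs) < 1e-12) {
    warning("flat cumulative skew; ori/ter undetermined")
    return(structure(list(ori = NA_integer_, ter = NA_integer_,
                          circular = circular, length = profile$length),
                     class = "ori_ter"))
  }
  centre <- profile$starts + profile$window %/% 2L
  ori <- centre[which.min(cs)]
  ter <- centre[which.max(cs)]
  if (ori == ter) {
    warning("ori and ter coincide; undetermined")
    return(structure(list(ori = NA_integer_, ter = NA_integer_,
                          circular = circular, length = profile$length),
                     class = "ori_ter"))
  }
  structure(list(ori = ori, ter = ter, circular = circular,
                 length = profile$length), class = "ori_ter")
}

#' Relative replichore position
#'
#' Maps a genomic coordinate to d in \[0,1\]: 0 at ori, 1 at ter,
#' linear along each replichore of the circular chromosome.  Invariant
#' under rotation of the coordinate origin.
#'
#' @param p 0-based position(s).
#' @param oriter a [locate_ori_ter()] result.
#' @param L genome length (defaults to the profile length).
#' @return numeric vector of relative positions.
#' @export
relative_position <- function(p, oriter, L = oriter$length) {
  ori <- oriter$ori; ter <- oriter$ter
  arc1 <- (ter - ori) %% L           # ori -> ter going forward
  arc2 <- L - arc1                   # ori -> ter going backward
  dfwd <- (p - ori) %% L             # forward distance ori -> p
  on_first <- dfwd <= arc1
  d <- ifelse(on_first, dfwd / arc1, ((ori - p) %% L) / arc2)
  as.numeric(d)
}

#' Cell-cycle methylation gradient analysis
#'
#' Bins methylation fractions by relative replichore position, compares
#' the ori region (d <= `edge`), ter region (d >= 1 - `edge`) and the
#' rest with two-sided rank-sum tests, and fits the hemimethylation
#' model m(d) = 1 - h0 * (1 - d) / 2 by least squares for the gradient
#' amplitude h0 (clamped to \[0,1\]).
#'
#' @param positions 0-based site coordinates on the concatenated
#'   replicon.
#' @param frac methylation fraction per site.
#' @param oriter a [locate_ori_ter()] result.
#' @param L genome length.
#' @param bins number of equal-width bins over d (default 20).
#' @param edge half-width defining the ori and ter region classes
#'   (default 0.1 of each replichore).
#' @return list with `h0`, `bin_means` (data.frame), `region_tests`
#'   (data.frame of pairwise rank-sum p-values), `d` per site.
#' @export
methylation_gradient <- function(positions, frac, oriter, L = oriter$length,
                                 bins = 20, edge = 0.1) {
  ok <- is.finite(frac)
  positions <- positions[ok]; frac <- frac[ok]
  if (length(frac) < 50L) stop("need at least 50 sites with a methylation fraction")
  d <- relative_position(positions, oriter, L)
  ## single-parameter least squares: frac = 1 - h0 * u, u = (1 - d)/2
  u <- (1 - d) / 2
  h0 <- sum(u * (1 - frac)) / sum(u^2)
  h0 <- clamp(h0, 0, 1)
  bin <- pmin(floor(d * bins), bins - 1)
  bin_means <- data.frame(
    bin = seq_len(bins) - 1L,
    d_mid = (seq_len(bins) - 0.5) / bins,
    mean_frac = as.numeric(tapply(frac, factor(bin, levels = 0:(bins - 1)), mean)),
    n = as.integer(table(factor(bin, levels = 0:(bins - 1)))))
  region <- ifelse(d <= edge, "ori", ifelse(d >= 1 - edge, "ter", "other"))
  pairs <- list(c("ori", "ter"), c("ori", "other"), c("ter", "other"))
  region_tests <- do.call(rbind, lapply(pairs, function(pr) {
    a <- frac[region == pr[1]]; b <- frac[region == pr[2]]
    p <- if (length(a) < 2L || length(b) < 2L) NA_real_ else
      suppressWarnings(stats::wilcox.test(a, b)$p.value)
    data.frame(region_a = pr[1], region_b = pr[2],
               median_a = if (length(a)) stats::median(a) else NA_real_,
               median_b = if (length(b)) stats::median(b) else NA_real_,
               p = p)
  }))
  list(h0 = h0, bin_means = bin_means, region_tests = region_tests, d = d)
}
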