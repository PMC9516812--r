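## Shared sequence utilities: IUPAC algebra, reverse complement, seed fan-out.

IUPAC_MAP <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", N = "N",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B"
)

#' Reverse complement of a DNA string
#'
#' Accepts the full IUPAC alphabet (so degenerate motifs can be
#' complemented, e.g. `revcomp("GANTC")` is `"GANTC"`).
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    ch <- rev(strsplit(toupper(s), "", fixed = TRUE)[[1]])
    bad <- !ch %in% names(IUPAC_COMPLEMENT)
    if (any(bad)) {
      stop("non-IUPAC character in sequence: ", paste(unique(ch[bad]), collapse = ","))
    }
    paste(IUPAC_COMPLEMENT[ch], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## IUPAC motif -> regex character classes. N in the *genome* never matches
## any motif symbol, so classes are built from concrete bases only.
iupac_to_regex <- function(motif) {
  ch <- strsplit(toupper(motif), "", fixed = TRUE)[[1]]
  bad <- !ch %in% names(IUPAC_MAP)
  if (any(bad)) stop("invalid IUPAC symbol in motif: ", paste(unique(ch[bad]), collapse = ","))
  paste(vapply(ch, function(s) {
    bases <- IUPAC_MAP[[s]]
    if (nchar(bases) == 1L) bases else paste0("[", bases, "]")
  }, character(1)), collapse = "")
}

is_valid_iupac <- function(motif) {
  ch <- strsplit(toupper(motif), "", fixed = TRUE)[[1]]
  length(ch) > 0L && all(ch %in% names(IUPAC_MAP))
}

## Does IUPAC string a denote the same base sets as b, position by position?
iupac_equal <- function(a, b) {
  if (nchar(a) != nchar(b)) return(FALSE)
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  all(vapply(seq_along(ca), function(i) {
    setequal(strsplit(IUPAC_MAP[[ca[i]]], "")[[1]], strsplit(IUPAC_MAP[[cb[i]]], "")[[1]])
  }, logical(1)))
}

## A motif is self-complementary (palindromic in the biological sense) when
## its reverse complement denotes the same degenerate pattern.
is_palindromic_motif <- function(motif) iupac_equal(motif, revcomp(motif))

## Deterministic fan-out of one user seed into independent substreams.
## Keeps all derived seeds below 2^31.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offs <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((abs(seed) * 48271 + offs * 16807 + 12345) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
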