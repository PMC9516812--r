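## Typed readers/writers for the external formats the pipeline touches.
##
## Coordinate conventions: everything is 0-based half-open internally.
## GFF3 (1-based inclusive) is converted at the read/write boundary; BED is
## already half-open.  Minus-strand per-base records are indexed by the
## plus-strand coordinate of the modified base.

VALID_KINGDOMS <- c("prokaryote", "eukaryote", "virus", "giant_virus")

#' Construct a genome object
#'
#' A genome is an ordered set of contigs (uppercase DNA over A,C,G,T,N)
#' with a kingdom tag used by breadth filtering.
#'
#' @param genome_id single string.
#' @param contigs named character vector of contig sequences; names are
#'   contig ids and must be unique.
#' @param kingdom one of `"prokaryote"`, `"eukaryote"`, `"virus"`,
#'   `"giant_virus"`.
#' @return an object of class `"genome"`.
#' @export
genome <- function(genome_id, contigs, kingdom = "prokaryote") {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  kingdom <- match.arg(kingdom, VALID_KINGDOMS)
  if (is.null(names(contigs)) || any(names(contigs) == "")) {
    stop("contigs must be a named character vector")
  }
  if (anyDuplicated(names(contigs))) {
    stop("duplicate contig id: ", names(contigs)[duplicated(names(contigs))][1])
  }
  contigs <- toupper(contigs)
  if (any(nchar(contigs) == 0L)) stop("empty contig sequence")
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad)) stop("contig ", names(contigs)[bad][1], " contains non-ACGTN characters")
  structure(list(genome_id = genome_id, contigs = contigs, kingdom = kingdom),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("<genome>", x$genome_id, sprintf("(%s)", x$kingdom), "\n")
  cat(" ", length(x$contigs), "contig(s),", sum(nchar(x$contigs)), "bp total\n")
  invisible(x)
}

#' Total genome length in bp
#' @param g a [genome()] object.
#' @return integer total length over contigs.
#' @export
genome_length <- function(g) sum(nchar(g$contigs))

#' Read a FASTA file
#'
#' Sequences are uppercased and U is mapped to T; characters outside the
#' IUPAC alphabet are rejected with the offending line number.  Ambiguity
#' codes other than N are accepted on input but stored as-is only when
#' `strict = FALSE`; by default anything outside A,C,G,T,N is an error
#' after U-mapping.
#'
#' @param path FASTA file.
#' @param genome_id id for the resulting genome (defaults to the file name).
#' @param kingdom kingdom tag, see [genome()].
#' @param strict reject IUPAC ambiguity codes other than N (default TRUE).
#' @return a [genome()] object.
#' @export
read_fasta <- function(path, genome_id = NULL,
                       kingdom = "prokaryote", strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  ids <- character(0); seqs <- character(0)
  cur_id <- NULL; cur <- character(0); header_line <- 0L
  flush <- function() {
    if (is.null(cur_id)) return()
    s <- paste(cur, collapse = "")
    if (nchar(s) == 0L) stop("empty sequence for '", cur_id, "' (line ", header_line, ")")
    ids <<- c(ids, cur_id); seqs <<- c(seqs, s)
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, ">")) {
      flush()
      cur_id <- sub("\\s.*$", "", substring(ln, 2))
      if (nchar(cur_id) == 0L) stop("malformed FASTA header at line ", i)
      header_line <- i; cur <- character(0)
    } else if (nzchar(trimws(ln))) {
      if (is.null(cur_id)) stop("sequence before first header at line ", i)
      s <- chartr("u", "t", toupper(trimws(ln)))
      s <- chartr("U", "T", s)
      ok <- if (strict) "[^ACGTN]" else "[^ACGTNRYSWKMBDHV]"
      if (grepl(ok, s)) stop("invalid sequence character at line ", i)
      cur <- c(cur, s)
    }
  }
  flush()
  if (length(ids) == 0L) stop("no sequences in ", path)
  if (anyDuplicated(ids)) stop("duplicate contig id: ", ids[duplicated(ids)][1])
  names(seqs) <- ids
  genome(genome_id %||% basename(path), seqs, kingdom = kingdom)
}

#' Write a genome to FASTA
#'
#' @param g a [genome()] object (or named character vector of sequences).
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta <- function(g, path, width = 70L) {
  contigs <- if (inherits(g, "genome")) g$contigs else g
  con <- file(path, "w"); on.exit(close(con))
  for (id in names(contigs)) {
    writeLines(paste0(">", id), con)
    s <- contigs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

validate_gene_table <- function(gt, contig_lengths = NULL) {
  need <- c("contig", "start", "end", "strand", "gene_id")
  if (!all(need %in% names(gt))) stop("gene table must have columns ", paste(need, collapse = ", "))
  if (any(gt$start < 0) || any(gt$start >= gt$end)) stop("gene table requires 0 <= start < end")
  if (!all(gt$strand %in% c("+", "-"))) stop("unknown strand symbol in gene table")
  if (anyDuplicated(gt$gene_id)) stop("duplicate gene_id: ", gt$gene_id[duplicated(gt$gene_id)][1])
  if (!is.null(contig_lengths)) {
    len <- contig_lengths[gt$contig]
    if (any(is.na(len))) stop("gene on unknown contig")
    if (any(gt$end > len)) stop("gene extends past contig end")
  }
  gt
}

#' Read a gene table (GFF3 or BED6)
#'
#' Both dialects are converted to the internal 0-based half-open
#' convention: GFF3 start is decremented, BED is taken as-is.
#'
#' @param path input file.
#' @param dialect `"gff3"` or `"bed"`.
#' @return data.frame with columns contig, start, end, strand, gene_id.
#' @export
read_gene_table <- function(path, dialect = c("gff3", "bed")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(data.frame(contig = character(0), start = integer(0), end = integer(0),
                      strand = character(0), gene_id = character(0)))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (dialect == "gff3") {
    gt <- do.call(rbind, lapply(seq_along(f), function(i) {
      x <- f[[i]]
      if (length(x) < 8L) stop("malformed GFF3 row at data line ", i)
      attr9 <- if (length(x) >= 9L) x[9] else ""
      id <- sub(".*(?:^|;)ID=([^;]+).*", "\\1", attr9, perl = TRUE)
      if (identical(id, attr9) || !nzchar(id)) id <- paste0("gene", i)
      data.frame(contig = x[1], start = as.integer(x[4]) - 1L,
                 end = as.integer(x[5]), strand = x[7], gene_id = id)
    }))
  } else {
    gt <- do.call(rbind, lapply(seq_along(f), function(i) {
      x <- f[[i]]
      if (length(x) < 6L) stop("malformed BED6 row at data line ", i)
      data.frame(contig = x[1], start = as.integer(x[2]), end = as.integer(x[3]),
                 strand = x[6], gene_id = x[4])
    }))
  }
  validate_gene_table(gt)
}

#' Write a gene table as GFF3
#' @param gt gene table (internal 0-based half-open coordinates).
#' @param path output file.
#' @export
write_gene_table <- function(gt, path) {
  validate_gene_table(gt)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\tmetaepi\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     gt$contig, gt$start + 1L, gt$end, gt$strand, gt$gene_id), con)
  invisible(path)
}

validate_modifications <- function(m) {
  need <- c("contig", "position", "strand", "mod_type", "coverage", "qv", "frac")
  if (!all(need %in% names(m))) stop("modification table must have columns ", paste(need, collapse = ", "))
  if (!all(m$strand %in% c("+", "-"))) stop("unknown strand symbol in modification record")
  if (any(m$coverage < 0) || any(m$qv < 0)) stop("negative coverage or qv")
  fr <- m$frac[!is.na(m$frac)]
  if (any(fr < 0 | fr > 1)) stop("frac outside [0,1]")
  m[order(m$contig, m$position, m$strand), , drop = FALSE]
}

#' Read per-site modification records
#'
#' Two dialects: a basemods-style GFF3 (1-based; score column is the
#' modification QV; attributes carry `coverage=` and `frac=`) and a plain
#' TSV with header `contig position strand mod_type coverage qv frac`
#' already in 0-based coordinates.
#'
#' @param path input file.
#' @param dialect `"basemods_gff"` or `"tsv"`.
#' @return data.frame of modification records, 0-based positions, sorted
#'   by (contig, position, strand).
#' @export
read_modifications <- function(path, dialect = c("basemods_gff", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    m <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c(contig = "character", strand = "character",
                                          mod_type = "character"))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    f <- strsplit(lines, "\t", fixed = TRUE)
    getattr <- function(a, key) {
      v <- sub(paste0(".*(?:^|;)", key, "=([^;]+).*"), "\\1", a, perl = TRUE)
      ifelse(v == a, NA, v)
    }
    m <- do.call(rbind, lapply(f, function(x) {
      if (length(x) < 9L) stop("malformed basemods GFF row")
      data.frame(contig = x[1],
                 position = as.integer(x[4]) - 1L,
                 strand = x[7],
                 mod_type = x[3],
                 coverage = as.integer(getattr(x[9], "coverage")),
                 qv = as.numeric(x[6]),
                 frac = as.numeric(getattr(x[9], "frac")))
    }))
  }
  m$mod_type[!m$mod_type %in% c("m6A", "m4C")] <- "unknown"
  validate_modifications(m)
}

#' Write modification records as TSV (0-based positions)
#' @param m modification records.
#' @param path output file.
#' @export
write_modifications <- function(m, path) {
  validate_modifications(m)
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample allele counts
#'
#' TSV with header `contig position ref sample nA nC nG nT`; positions are
#' 0-based; one row per (position, sample).
#'
#' @param path input file.
#' @return validated data.frame.
#' @export
read_allele_counts <- function(path) {
  ac <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c(contig = "character", ref = "character",
                                         sample = "character"))
  validate_allele_counts(ac)
}

validate_allele_counts <- function(ac) {
  need <- c("contig", "position", "ref", "sample", "nA", "nC", "nG", "nT")
  if (!all(need %in% names(ac))) stop("allele counts must have columns ", paste(need, collapse = ", "))
  if (!all(ac$ref %in% c("A", "C", "G", "T"))) stop("ref_base must be one of A,C,G,T")
  cnt <- as.matrix(ac[, c("nA", "nC", "nG", "nT")])
  if (any(cnt < 0)) stop("negative allele count")
  ac
}

#' Write allele counts TSV
#' @param ac allele counts table.
#' @param path output file.
#' @export
write_allele_counts <- function(ac, path) {
  validate_allele_counts(ac)
  utils::write.table(ac, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pairwise hits table (query, subject, bit_score)
#' @param path TSV with header `query subject bit_score`.
#' @return validated data.frame.
#' @export
read_hits_table <- function(path) {
  h <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c(query = "character", subject = "character"))
  if (!all(c("query", "subject", "bit_score") %in% names(h))) {
    stop("hits table must have columns query, subject, bit_score")
  }
  if (any(h$bit_score < 0)) stop("negative bit score")
  h
}

#' Write a hits table TSV
#' @param h hits table.
#' @param path output file.
#' @export
write_hits_table <- function(h, path) {
  if (any(h$bit_score < 0)) stop("negative bit score")
  utils::write.table(h, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a symmetric distance matrix
#'
#' Checks finiteness, non-negativity, zero diagonal and symmetry (1e-9);
#' returns the matrix with symmetry enforced exactly.
#'
#' @param m square numeric matrix with dimnames.
#' @return the validated matrix.
#' @export
as_distance_matrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (is.null(rownames(m))) stop("distance matrix must be labelled")
  if (any(!is.finite(m))) stop("non-finite distance")
  if (any(m < -1e-12)) stop("negative distance")
  if (max(abs(m - t(m))) > 1e-9) stop("distance matrix not symmetric")
  if (any(abs(diag(m)) > 1e-12)) stop("distance matrix diagonal not zero")
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

#' Write a distance matrix as CSV
#' @param dm distance matrix.
#' @param path output file.
#' @export
write_matrix <- function(dm, path) {
  dm <- as_distance_matrix(dm)
  utils::write.csv(as.data.frame(dm), path, row.names = TRUE)
  invisible(path)
}

#' Read a distance matrix written by [write_matrix()]
#' @param path CSV file.
#' @return validated matrix.
#' @export
read_matrix <- function(path) {
  d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as_distance_matrix(as.matrix(d))
}

#' Write a tree in Newick format
#' @param tree an `ape::phylo` object.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path Newick file.
#' @return an `ape::phylo` object.
#' @export
read_newick <- function(path) ape::read.tree(path)
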