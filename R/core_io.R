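# Readers/writers for the standard formats the pipeline touches, genome
# windowing, and elementary sequence tracks.
#
# All coordinates are 0-based half-open internally (BED convention).  The
# "coords" alignment dialect is 1-based fully-closed on disk and converted
# on read.

#' Genomic interval table
#'
#' Constructs a validated data frame of genomic intervals in 0-based
#' half-open coordinates.
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive.
#' @param end integer vector, exclusive; must satisfy `start < end`.
#' @param strand optional strand vector in `+`, `-`, `*`.
#' @return data.frame with columns chrom, start, end, strand.
#' @export
genomic_intervals <- function(chrom, start, end, strand = NULL) {
  if (length(chrom) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  if (is.null(strand)) strand <- rep("*", length(chrom))
  stopifnot(length(start) == length(chrom), length(end) == length(chrom))
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(end <= start)) stop("interval end must exceed start")
  if (!all(strand %in% c("+", "-", "*"))) stop("strand must be +, - or *")
  data.frame(chrom = as.character(chrom), start = as.numeric(start),
             end = as.numeric(end), strand = as.character(strand),
             stringsAsFactors = FALSE)
}

#' Per-chromosome fixed-width window track
#'
#' A `window_track` stores one real value per non-overlapping window of
#' fixed width tiling a chromosome from position 0; the last window is
#' truncated at the chromosome end.  Missing windows carry `NA`, never 0.
#'
#' @param chrom chromosome name.
#' @param window_size window width in bp.
#' @param values numeric vector, one value per window (`NA` = missing).
#' @param chrom_length chromosome length in bp; when supplied the number
#'   of values must equal `ceiling(chrom_length / window_size)`.
#' @return object of class `window_track`.
#' @export
window_track <- function(chrom, window_size, values, chrom_length = NULL) {
  if (window_size < 1) stop("window_size must be >= 1")
  if (is.null(chrom_length)) chrom_length <- length(values) * window_size
  n_expect <- ceiling(chrom_length / window_size)
  if (length(values) != n_expect)
    stop(sprintf("expected %d windows for length %d at size %d, got %d",
                 n_expect, chrom_length, window_size, length(values)))
  structure(list(chrom = as.character(chrom),
                 window_size = as.numeric(window_size),
                 values = as.numeric(values),
                 chrom_length = as.numeric(chrom_length)),
            class = "window_track")
}

#' @export
print.window_track <- function(x, ...) {
  cat(sprintf("window_track: %s, %d x %g bp windows (%d missing)\n",
              x$chrom, length(x$values), x$window_size,
              sum(is.na(x$values))))
  invisible(x)
}

#' Window start coordinates of a track
#' @param track a `window_track`.
#' @return numeric vector of 0-based window starts.
#' @export
track_starts <- function(track) {
  (seq_along(track$values) - 1) * track$window_size
}

#' Read a FASTA file
#'
#' Sequence names are truncated at the first whitespace and sequences are
#' uppercased.
#'
#' @param path path to a FASTA file.
#' @return named character vector of uppercase sequences, order preserved.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1L)
  seqs
}

#' Write sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Tile chromosomes into non-overlapping windows
#'
#' @param chrom_lengths named numeric vector (or list) of chromosome
#'   lengths in bp.
#' @param window_size window width in bp, >= 1.
#' @return interval data.frame (see [genomic_intervals()]); every base is
#'   covered exactly once, the last window of each chromosome truncated.
#' @export
make_windows <- function(chrom_lengths, window_size) {
  if (window_size <= 0) stop("window_size must be positive")
  chrom_lengths <- unlist(chrom_lengths)
  out <- lapply(names(chrom_lengths), function(cn) {
    len <- chrom_lengths[[cn]]
    starts <- seq(0, len - 1, by = window_size)
    genomic_intervals(rep(cn, length(starts)), starts,
                      pmin(starts + window_size, len))
  })
  do.call(rbind, out)
}

#' Windowed GC content of a sequence
#'
#' Fraction (G+C)/(A+C+G+T) per window; N bases are excluded from the
#' denominator and windows with at least `max_n_frac` N are missing.
#'
#' @param seq a character string over A,C,G,T,N.
#' @param window_size window width in bp.
#' @param max_n_frac windows with >= this fraction of N are set missing.
#' @param chrom chromosome name recorded on the track.
#' @return a [window_track()] of GC fractions in \[0,1\].
#' @export
gc_track <- function(seq, window_size, max_n_frac = 0.5, chrom = "seq") {
  if (nchar(seq) == 0) stop("empty sequence")
  n <- nchar(seq)
  starts <- seq(1, n, by = window_size)
  vals <- vapply(starts, function(s) {
    w <- substr(seq, s, min(s + window_size - 1, n))
    tab <- table(strsplit(w, "")[[1]])
    nN <- sum(tab[names(tab) == "N"])
    wlen <- nchar(w)
    if (nN >= max_n_frac * wlen || wlen == nN) return(NA_real_)
    gc <- sum(tab[names(tab) %in% c("G", "C")])
    gc / (wlen - nN)
  }, numeric(1))
  window_track(chrom, window_size, vals, chrom_length = n)
}

#' Alignment block table
#'
#' @param query_chrom,query_start,query_end query interval (0-based
#'   half-open).
#' @param target_chrom,target_start,target_end target interval.
#' @param strand `+` or `-`.
#' @param matches identical columns in the alignment.
#' @param aln_len aligned columns; `matches <= aln_len`.
#' @return data.frame with one row per block and an `identity` column
#'   `matches/aln_len`.
#' @export
alignment_blocks <- function(query_chrom, query_start, query_end,
                             target_chrom, target_start, target_end,
                             strand, matches, aln_len) {
  if (any(matches > aln_len)) stop("matches must not exceed aln_len")
  if (any(aln_len <= 0)) stop("aln_len must be positive")
  if (!all(strand %in% c("+", "-"))) stop("strand must be + or -")
  if (any(query_end <= query_start) || any(target_end <= target_start))
    stop("intervals must have positive length")
  data.frame(query_chrom = as.character(query_chrom),
             query_start = as.numeric(query_start),
             query_end = as.numeric(query_end),
             target_chrom = as.character(target_chrom),
             target_start = as.numeric(target_start),
             target_end = as.numeric(target_end),
             strand = as.character(strand),
             matches = as.numeric(matches),
             aln_len = as.numeric(aln_len),
             identity = as.numeric(matches) / as.numeric(aln_len),
             stringsAsFactors = FALSE)
}

#' Read pairwise alignment blocks
#'
#' Two dialects are supported: `paf` (minimap2-style, columns 1-12,
#' 0-based half-open on disk) and `coords` (a nucmer-show-coords-like TSV
#' with columns query, qstart, qend, target, tstart, tend, strand,
#' matches, aln_len; 1-based fully-closed on disk, converted on read).
#'
#' @param path input file.
#' @param dialect `"paf"` or `"coords"`.
#' @param min_len drop blocks with `aln_len` below this (default keep all).
#' @param min_identity drop blocks below this identity (default keep all).
#' @return an [alignment_blocks()] data.frame.
#' @export
read_alignment_blocks <- function(path, dialect = c("paf", "coords"),
                                  min_len = 0, min_identity = 0) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0)
    return(alignment_blocks(character(), numeric(), numeric(), character(),
                            numeric(), numeric(), character(), numeric(),
                            numeric())[0, ])
  fields <- strsplit(lines, "\t")
  if (dialect == "paf") {
    bad <- which(vapply(fields, length, 0L) < 12L)
    if (length(bad)) stop("malformed PAF at line ", bad[1])
    g <- function(i) vapply(fields, `[`, "", i)
    gn <- function(i) as.numeric(g(i))
    blk <- alignment_blocks(g(1), gn(3), gn(4), g(6), gn(8), gn(9),
                            g(5), gn(10), gn(11))
  } else {
    bad <- which(vapply(fields, length, 0L) < 9L)
    if (length(bad)) stop("malformed coords table at line ", bad[1])
    g <- function(i) vapply(fields, `[`, "", i)
    gn <- function(i) as.numeric(g(i))
    # 1-based fully-closed -> 0-based half-open
    blk <- alignment_blocks(g(1), gn(2) - 1, gn(3), g(4), gn(5) - 1, gn(6),
                            g(7), gn(8), gn(9))
  }
  blk[blk$aln_len >= min_len & blk$identity >= min_identity, , drop = FALSE]
}

#' Write alignment blocks as PAF
#'
#' Query/target lengths default to the maximum end seen per sequence;
#' supply them for faithful headers.
#'
#' @param blocks an [alignment_blocks()] data.frame.
#' @param path output path.
#' @param query_lengths,target_lengths optional named vectors of sequence
#'   lengths.
#' @return `path`, invisibly.
#' @export
write_paf <- function(blocks, path, query_lengths = NULL,
                      target_lengths = NULL) {
  qlen <- if (is.null(query_lengths))
    tapply(blocks$query_end, blocks$query_chrom, max) else query_lengths
  tlen <- if (is.null(target_lengths))
    tapply(blocks$target_end, blocks$target_chrom, max) else target_lengths
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d",
                   blocks$query_chrom, as.integer(qlen[blocks$query_chrom]),
                   as.integer(blocks$query_start),
                   as.integer(blocks$query_end),
                   blocks$strand, blocks$target_chrom,
                   as.integer(tlen[blocks$target_chrom]),
                   as.integer(blocks$target_start),
                   as.integer(blocks$target_end),
                   as.integer(blocks$matches), as.integer(blocks$aln_len),
                   60L)
  writeLines(lines, path)
  invisible(path)
}

#' Read a contact matrix from COO triplet text
#'
#' Lines are `bin_i bin_j count` with 0-based bin indices; the matrix is
#' symmetrized (each triplet fills both (i,j) and (j,i)).
#'
#' @param path triplet file.
#' @param n_bins number of bins.
#' @param chrom,bin_size metadata recorded on the object.
#' @return a [contact_matrix()].
#' @export
read_contacts_coo <- function(path, n_bins, chrom = "chr", bin_size = 1) {
  tab <- utils::read.table(path, col.names = c("i", "j", "x"))
  m <- matrix(0, n_bins, n_bins)
  m[cbind(tab$i + 1, tab$j + 1)] <- tab$x
  m[cbind(tab$j + 1, tab$i + 1)] <- tab$x
  contact_matrix(chrom, bin_size, m)
}

#' Write a contact matrix as COO triplet text (upper triangle incl. diagonal)
#' @param m a [contact_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contacts_coo <- function(m, path) {
  idx <- which(upper.tri(m$counts, diag = TRUE) & m$counts != 0,
               arr.ind = TRUE)
  lines <- sprintf("%d\t%d\t%g", idx[, 1] - 1L, idx[, 2] - 1L,
                   m$counts[idx])
  writeLines(lines, path)
  invisible(path)
}

#' Write intervals as BED
#' @param intervals interval data.frame; optional `name` and `score`
#'   columns become BED columns 4-5.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- list(intervals$chrom, as.integer(intervals$start),
               as.integer(intervals$end))
  if (!is.null(intervals$name)) {
    cols <- c(cols, list(intervals$name))
    if (!is.null(intervals$score)) {
      cols <- c(cols, list(intervals$score))
      if (!is.null(intervals$strand)) cols <- c(cols, list(intervals$strand))
    }
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Export a window track as bedGraph
#' @param track a [window_track()]; missing windows are omitted.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  starts <- track_starts(track)
  keep <- !is.na(track$values)
  lines <- sprintf("%s\t%d\t%d\t%g", track$chrom,
                   as.integer(starts[keep]),
                   as.integer(pmin(starts[keep] + track$window_size,
                                   track$chrom_length)),
                   track$values[keep])
  writeLines(lines, path)
  invisible(path)
}

#' Reverse-complement a DNA string
#' @param seq character string over A,C,G,T,N.
#' @return reverse-complemented string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
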