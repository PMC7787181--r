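# Windowed repeat-enrichment annotation of putative centromeres,
# telomeres and interstitial telomeric repeats (ITRs), and detection of
# chrW-style palindromes by inverted-repeat self-comparison with k-mer
# seeds.

#' Count motif occurrences per window on both strands
#'
#' Occurrences of the motif and of its reverse complement, allowing up
#' to `max_mismatch` mismatches, are counted at distinct start
#' positions (overlaps allowed) and binned into non-overlapping
#' windows by start position.
#'
#' @param seq character string over A,C,G,T,N.
#' @param motif motif sequence, length >= 4.
#' @param window_size window width (bp); the field default for repeat
#'   enrichment is 50 kb.
#' @param max_mismatch allowed mismatches per occurrence.
#' @param chrom name recorded on the track.
#' @return a [window_track()] of counts.
#' @export
count_motif_windows <- function(seq, motif, window_size = 50000,
                                max_mismatch = 0, chrom = "seq") {
  if (nchar(motif) < 4) stop("motif length must be >= 4")
  subject <- Biostrings::DNAString(seq)
  starts <- integer(0)
  rc <- revcomp(motif)
  for (pat in unique(c(motif, rc))) {
    m <- Biostrings::matchPattern(pat, subject,
                                  max.mismatch = max_mismatch)
    starts <- c(starts, Biostrings::start(m))
  }
  n <- nchar(seq)
  n_win <- ceiling(n / window_size)
  counts <- tabulate(floor((starts - 1) / window_size) + 1, n_win)
  window_track(chrom, window_size, counts, chrom_length = n)
}

# merge enriched windows (track values >= min_count) across gaps of at
# most merge_gap windows; returns intervals with summed counts
.enriched_intervals <- function(track, min_count, merge_gap) {
  hit <- which(!is.na(track$values) & track$values >= min_count)
  if (!length(hit)) return(NULL)
  grp <- cumsum(c(1, diff(hit) > merge_gap + 1))
  ws <- track$window_size
  do.call(rbind, lapply(split(hit, grp), function(ix) {
    data.frame(chrom = track$chrom, start = (min(ix) - 1) * ws,
               end = min(max(ix) * ws, track$chrom_length),
               copies = sum(track$values[min(ix):max(ix)],
                            na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
}

#' Call putative centromeres from windowed monomer counts
#'
#' Windows with at least `min_copies` monomer matches are merged across
#' gaps of at most `merge_gap` windows; with `one_per_chrom` the
#' interval with the highest summed count is primary and the rest are
#' secondary.
#'
#' @param track monomer-count [window_track()] (use
#'   [count_motif_windows()] with `max_mismatch` about 10 percent of
#'   the monomer length).
#' @param min_copies per-window call threshold.
#' @param merge_gap merge gap in windows.
#' @param one_per_chrom report a single primary centromere.
#' @return data.frame: chrom, start, end, copies, kind = "centromere",
#'   primary (logical); zero rows when nothing is enriched.
#' @export
call_centromeres <- function(track, min_copies = 20, merge_gap = 1,
                             one_per_chrom = TRUE) {
  iv <- .enriched_intervals(track, min_copies, merge_gap)
  if (is.null(iv))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), copies = numeric(),
                      kind = character(), primary = logical()))
  iv$kind <- "centromere"
  iv$primary <- if (one_per_chrom)
    seq_len(nrow(iv)) == which.max(iv$copies) else TRUE
  iv[order(-iv$primary, iv$start), ]
}

#' Call telomere arrays and interstitial telomeric repeats
#'
#' Enriched merged intervals from a telomere-motif count track are
#' classified `telomere_terminal` when within `terminal_margin`
#' windows of a chromosome end, otherwise `ITR`.
#'
#' @param track telomere-motif count [window_track()].
#' @param min_copies per-window call threshold.
#' @param terminal_margin distance from a chromosome end, in windows,
#'   within which a call is terminal.
#' @param merge_gap merge gap in windows.
#' @return data.frame: chrom, start, end, copies, kind.
#' @export
call_telomeres <- function(track, min_copies = 100, terminal_margin = 2,
                           merge_gap = 1) {
  iv <- .enriched_intervals(track, min_copies, merge_gap)
  if (is.null(iv))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), copies = numeric(),
                      kind = character()))
  margin_bp <- terminal_margin * track$window_size
  terminal <- iv$start < margin_bp |
    iv$end > track$chrom_length - margin_bp
  iv$kind <- ifelse(terminal, "telomere_terminal", "ITR")
  iv
}

#' Detect palindromes (large inverted repeats) by k-mer seeding
#'
#' Exact k-mers of the sequence are matched against the k-mers of its
#' reverse complement; a matched pair at forward positions (p, q)
#' lies on the anti-diagonal p + q of the self-comparison dot plot, so
#' gap-free inverted-repeat arms collect as seed groups with constant
#' p + q.  Each group is turned into an arm pair, arm identity is
#' computed by gap-free column comparison of arm1 versus the reverse
#' complement of arm2, and calls are filtered by arm length, spacer
#' length and identity.  Overlapping calls keep the longest.
#'
#' @param seq character string.
#' @param k seed k-mer size.
#' @param min_arm minimum arm length (bp).
#' @param max_spacer maximum gap between the arms (bp).
#' @param min_identity minimum arm identity.
#' @param chrom name recorded on the calls.
#' @return data.frame: chrom, arm1_start, arm1_end, arm2_start,
#'   arm2_end (0-based half-open), spacer, arm_len, total_length,
#'   identity.
#' @export
find_palindromes <- function(seq, k = 21, min_arm = 2000,
                             max_spacer = 50000, min_identity = 0.9,
                             chrom = "seq") {
  if (k > min_arm) stop("k must not exceed min_arm")
  if (nchar(seq) < 2 * min_arm) stop("sequence shorter than two arms")
  n <- nchar(seq)
  empty <- data.frame(chrom = character(), arm1_start = numeric(),
                      arm1_end = numeric(), arm2_start = numeric(),
                      arm2_end = numeric(), spacer = numeric(),
                      arm_len = numeric(), total_length = numeric(),
                      identity = numeric())
  pos <- seq_len(n - k + 1)
  kmers <- substring(seq, pos, pos + k - 1)
  rcseq <- revcomp(seq)
  rkmers <- substring(rcseq, pos, pos + k - 1)
  # rc k-mer at rc-position r covers forward positions
  # (n - r - k + 2)..(n - r + 1); forward start q = n - r - k + 2
  idx <- match(rkmers, kmers)            # first match is enough to seed
  hit <- which(!is.na(idx) & !grepl("N", rkmers, fixed = TRUE))
  if (!length(hit)) return(empty)
  p <- idx[hit]                          # forward arm1 seed start
  q <- n - hit - k + 2                   # forward arm2 seed start
  keep <- p < q
  p <- p[keep]; q <- q[keep]
  if (!length(p)) return(empty)
  cv <- strsplit(seq, "")[[1]]
  compv <- chartr("ACGTN", "TGCAN", cv)  # complement, unreversed
  diag_id <- p + q
  calls <- list()
  for (d in unique(diag_id)) {
    ps <- sort(p[diag_id == d])
    # split distant seed runs on the same anti-diagonal
    grp <- cumsum(c(1, diff(ps) > min_arm))
    for (g in split(ps, grp)) {
      a1s <- min(g); a1e <- max(g) + k   # 1-based arm1 [a1s, a1e)
      # base i of arm1 pairs with base s - i of arm2
      s <- d + k - 1
      # x-drop extension over isolated mismatches: +1 match, -2
      # mismatch, stop when the running score drops 10 below its
      # maximum; the endpoint is the last argmax column
      extend <- function(from, step, lim) {
        i <- from; best_i <- from - step
        run <- 0; best <- 0
        while (i >= 1 && i <= n && s - i >= 1 && s - i <= n &&
               (if (step > 0) i <= lim else i >= lim)) {
          run <- run + if (cv[i] != "N" && cv[i] == compv[s - i])
            1 else -2
          if (run > best) { best <- run; best_i <- i }
          if (run < best - 10) break
          i <- i + step
        }
        best_i
      }
      a1s <- min(a1s, extend(a1s - 1L, -1L, 1L))
      inner_lim <- floor((s - 1) / 2)    # arms must not cross
      a1e <- max(a1e, extend(a1e, 1L, inner_lim) + 1L)
      arm_len <- a1e - a1s
      if (arm_len < min_arm) next
      a2s <- d - a1e + k                 # arm2 start pairs with arm1 end
      a2e <- d - a1s + k
      spacer <- a2s - a1e
      if (spacer < 0 || spacer > max_spacer) next
      arm1 <- substr(seq, a1s, a1e - 1)
      arm2 <- substr(seq, a2s, a2e - 1)
      ident <- mean(strsplit(arm1, "")[[1]] ==
                      strsplit(revcomp(arm2), "")[[1]])
      if (ident < min_identity) next
      calls[[length(calls) + 1L]] <- data.frame(
        chrom = chrom, arm1_start = a1s - 1, arm1_end = a1e - 1,
        arm2_start = a2s - 1, arm2_end = a2e - 1, spacer = spacer,
        arm_len = arm_len, total_length = (a2e - 1) - (a1s - 1),
        identity = ident, stringsAsFactors = FALSE)
    }
  }
  if (!length(calls)) return(empty)
  out <- do.call(rbind, calls)
  out <- out[order(-out$total_length), ]
  # overlapping calls: keep the longest
  kept <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!kept[i]) next
    if (i < nrow(out)) for (j in (i + 1):nrow(out)) {
      if (!kept[j]) next
      if (out$arm1_start[j] < out$arm2_end[i] &&
          out$arm2_end[j] > out$arm1_start[i]) kept[j] <- FALSE
    }
  }
  out <- out[kept, ]
  out <- out[order(out$arm1_start), ]
  rownames(out) <- NULL
  out
}
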