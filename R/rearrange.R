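# Chain alignment blocks into syntenic runs, call and polarize
# inversions, extract breakpoints, and test breakpoint association
# with TAD boundaries and insulation.

#' Chain collinear alignment blocks into syntenic runs
#'
#' Greedy left-to-right chaining of strand-consistent, order-consistent
#' blocks with inter-block gaps at most `max_gap` in both genomes.
#' Input order does not matter (blocks are sorted by query start).
#'
#' @param blocks [alignment_blocks()] between one query and one target
#'   chromosome.
#' @param max_gap maximum gap (bp) between consecutive chained blocks.
#' @param min_block drop blocks shorter than this before chaining.
#' @return data.frame of chains: chain_id, strand, query_start,
#'   query_end, target_start, target_end, n_blocks, matches, aln_len.
#' @export
chain_synteny <- function(blocks, max_gap = 1e5, min_block = 1000) {
  b <- blocks[blocks$aln_len >= min_block, , drop = FALSE]
  if (nrow(b) == 0)
    return(data.frame(chain_id = integer(), strand = character(),
                      query_start = numeric(), query_end = numeric(),
                      target_start = numeric(), target_end = numeric(),
                      n_blocks = integer(), matches = numeric(),
                      aln_len = numeric()))
  if (length(unique(b$query_chrom)) > 1 ||
      length(unique(b$target_chrom)) > 1)
    stop("chain_synteny expects a single chromosome pair")
  b <- b[order(b$query_start), ]
  n <- nrow(b)
  chain_id <- integer(n)
  chain_id[1] <- 1L
  for (i in 2:max(n, 2)) {
    if (i > n) break
    prev <- i - 1L
    same <- b$strand[i] == b$strand[prev]
    qgap <- b$query_start[i] - b$query_end[prev]
    tgap <- if (b$strand[i] == "+")
      b$target_start[i] - b$target_end[prev]
    else
      b$target_start[prev] - b$target_end[i]
    ok <- same && qgap <= max_gap && qgap >= -max_gap / 10 &&
      tgap <= max_gap && tgap >= -max_gap / 10
    chain_id[i] <- if (ok) chain_id[prev] else chain_id[prev] + 1L
  }
  agg <- lapply(split(seq_len(n), chain_id), function(ix) {
    data.frame(chain_id = chain_id[ix[1]], strand = b$strand[ix[1]],
               query_start = min(b$query_start[ix]),
               query_end = max(b$query_end[ix]),
               target_start = min(b$target_start[ix]),
               target_end = max(b$target_end[ix]),
               n_blocks = length(ix), matches = sum(b$matches[ix]),
               aln_len = sum(b$aln_len[ix]))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Call inversions from synteny chains
#'
#' A reverse-strand chain flanked by forward chains (or chromosome
#' ends) whose query span is at least `min_len` becomes an inversion.
#'
#' @param chains output of [chain_synteny()], one chromosome pair.
#' @param min_len minimum inversion query span (bp); the field default
#'   is 10 kb.
#' @param query_chrom chromosome name recorded on the calls.
#' @return data.frame: chrom, start, end (query coordinates), length,
#'   target_start, target_end, n_blocks, lineage (`"unpolarized"`).
#' @export
call_inversions <- function(chains, min_len = 10000,
                            query_chrom = "chr") {
  neg <- chains[chains$strand == "-", , drop = FALSE]
  neg <- neg[neg$query_end - neg$query_start >= min_len, , drop = FALSE]
  if (nrow(neg) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), length = numeric(),
                      target_start = numeric(), target_end = numeric(),
                      n_blocks = integer(), lineage = character()))
  out <- data.frame(chrom = query_chrom, start = neg$query_start,
                    end = neg$query_end,
                    length = neg$query_end - neg$query_start,
                    target_start = neg$target_start,
                    target_end = neg$target_end,
                    n_blocks = neg$n_blocks, lineage = "unpolarized",
                    stringsAsFactors = FALSE)
  out[order(out$start), ]
}

#' Polarize inversions with an outgroup
#'
#' For each inversion called between the focal genome and species B,
#' the majority strand (weighted by aligned length) of outgroup blocks
#' overlapping the inversion's query interval decides the lineage:
#' outgroup reversed (agrees with B) means the inversion happened on
#' the focal lineage; outgroup forward (agrees with the focal
#' arrangement) means it happened on the B lineage ("other").
#' Inversions with under `min_coverage` outgroup coverage stay
#' unpolarized.
#'
#' @param inversions data.frame from [call_inversions()].
#' @param outgroup_blocks [alignment_blocks()] focal vs outgroup on the
#'   same query chromosome.
#' @param min_coverage required fraction of the inversion covered by
#'   outgroup alignment.
#' @return `inversions` with the lineage column filled in
#'   (`focal`/`other`/`unpolarized`).
#' @export
polarize_inversions <- function(inversions, outgroup_blocks,
                                min_coverage = 0.5) {
  if (nrow(inversions) == 0) return(inversions)
  for (i in seq_len(nrow(inversions))) {
    s <- inversions$start[i]; e <- inversions$end[i]
    ov <- pmin(outgroup_blocks$query_end, e) -
      pmax(outgroup_blocks$query_start, s)
    hit <- ov > 0
    cov <- sum(ov[hit]) / (e - s)
    if (cov < min_coverage) {
      inversions$lineage[i] <- "unpolarized"
      next
    }
    w_neg <- sum(ov[hit][outgroup_blocks$strand[hit] == "-"])
    w_pos <- sum(ov[hit]) - w_neg
    inversions$lineage[i] <- if (w_neg > w_pos) "focal" else "other"
  }
  inversions
}

#' Inversion breakpoints
#'
#' Two intervals per inversion at the query interval ends, widened by
#' `pad` on both sides and clipped to the chromosome.
#'
#' @param inversions data.frame from [call_inversions()].
#' @param pad half-width added to each side (bp).
#' @param chrom_length clip upper bound (default: no clipping).
#' @return interval data.frame with an `inversion` index column.
#' @export
breakpoints <- function(inversions, pad = 0, chrom_length = Inf) {
  if (nrow(inversions) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), inversion = integer()))
  pos <- c(rbind(inversions$start, inversions$end))
  idx <- rep(seq_len(nrow(inversions)), each = 2)
  st <- pmax(0, pos - pad)
  en <- pmin(chrom_length, pos + pad + 1)
  data.frame(chrom = rep(inversions$chrom, each = 2), start = st,
             end = en, inversion = idx, stringsAsFactors = FALSE)
}

#' Breakpoint-boundary overlap with a permutation test
#'
#' Observed statistic: breakpoints lying within `slack` of any TAD
#' boundary.  Null: breakpoints re-placed uniformly on the chromosome
#' (count preserved), `n_perm` draws under `seed`;
#' p = (1 + #(perm >= observed)) / (1 + n_perm).  Also classifies each
#' inversion by whether both, one or neither of its breakpoints hits a
#' boundary.
#'
#' @param bp breakpoint data.frame from [breakpoints()] (needs start
#'   and inversion columns).
#' @param boundaries data.frame with a `start` column (bp).
#' @param chrom_length chromosome length for the uniform null.
#' @param slack matching distance (bp); default one 10-kb Hi-C bin.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @param exclude optional interval data.frame; null placements are
#'   redrawn until outside these regions.
#' @return list: observed, perm_mean, perm_sd, p, n_perm, seed,
#'   categories (named counts both/one/neither).
#' @export
breakpoint_boundary_overlap <- function(bp, boundaries, chrom_length,
                                        slack = 10000, n_perm = 1000,
                                        seed = 1, exclude = NULL) {
  if (nrow(bp) == 0) stop("no breakpoints supplied")
  if (n_perm < 100) stop("n_perm must be >= 100")
  bpos <- boundaries$start
  hits <- function(pos) {
    if (!length(bpos)) return(rep(FALSE, length(pos)))
    vapply(pos, function(p) any(abs(bpos - p) <= slack), logical(1))
  }
  obs_hit <- hits(bp$start)
  observed <- sum(obs_hit)
  set.seed(seed)
  draw <- function(n) {
    pos <- stats::runif(n, 0, chrom_length)
    if (!is.null(exclude) && nrow(exclude)) {
      for (tries in 1:50) {
        bad <- vapply(pos, function(p)
          any(exclude$start <= p & p < exclude$end), logical(1))
        if (!any(bad)) break
        pos[bad] <- stats::runif(sum(bad), 0, chrom_length)
      }
    }
    pos
  }
  perm <- vapply(seq_len(n_perm), function(i)
    sum(hits(draw(nrow(bp)))), numeric(1))
  p <- (1 + sum(perm >= observed)) / (1 + n_perm)
  per_inv <- tapply(obs_hit, bp$inversion, sum)
  categories <- c(both = sum(per_inv == 2), one = sum(per_inv == 1),
                  neither = sum(per_inv == 0))
  list(observed = observed, perm_mean = mean(perm),
       perm_sd = stats::sd(perm), p = p, n_perm = n_perm, seed = seed,
       categories = categories)
}

#' Compare a window track between two region sets
#'
#' Wilcoxon rank-sum test (normal approximation with tie correction)
#' of the track values overlapping region set A versus set B — e.g.,
#' insulation at inversion breakpoints versus TAD interiors.
#'
#' @param track a [window_track()].
#' @param regions_a,regions_b interval data.frames on the track's
#'   chromosome.
#' @return list: statistic (W), p (two-sided), n_a, n_b, median_a,
#'   median_b.
#' @export
compare_region_values <- function(track, regions_a, regions_b) {
  starts <- track_starts(track)
  ends <- pmin(starts + track$window_size, track$chrom_length)
  pick <- function(regions) {
    keep <- rep(FALSE, length(starts))
    for (i in seq_len(nrow(regions)))
      keep <- keep | (starts < regions$end[i] & ends > regions$start[i])
    track$values[keep & !is.na(track$values)]
  }
  a <- pick(regions_a); b <- pick(regions_b)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values")
  wt <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n_a = length(a), n_b = length(b),
       median_a = stats::median(a), median_b = stats::median(b))
}
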