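# Order W scaffolds along the (outgroup) Z, compute windowed W/Z
# divergence, and segment the divergence series into evolutionary
# strata with a least-squares changepoint dynamic program selected by
# BIC.

#' Place W scaffolds on the Z chromosome by best unique alignment
#'
#' Blocks of each W scaffold are clustered into candidate Z loci
#' (cluster gap `locus_gap`); each locus is scored by summed matches.
#' A scaffold is placed at its best locus only when the best score
#' exceeds the runner-up by `min_unique_margin`; otherwise it is
#' reported unplaced.
#'
#' @param blocks [alignment_blocks()] of W scaffolds (query) vs one Z
#'   chromosome (target).
#' @param min_unique_margin required best/runner-up score ratio.
#' @param locus_gap maximum target gap joining blocks into one locus.
#' @return data.frame ordered by Z coordinate: scaffold, z_start, z_end,
#'   score, placed (logical; unplaced rows sort last with NA position).
#' @export
place_w_on_z <- function(blocks, min_unique_margin = 1.2,
                         locus_gap = 1e5) {
  if (length(unique(blocks$target_chrom)) > 1)
    stop("blocks must share one Z target")
  res <- lapply(split(blocks, blocks$query_chrom), function(b) {
    b <- b[order(b$target_start), ]
    new_locus <- c(TRUE, b$target_start[-1] >
                     utils::head(b$target_end, -1) + locus_gap)
    locus <- cumsum(new_locus)
    score <- tapply(b$matches, locus, sum)
    st <- tapply(b$target_start, locus, min)
    en <- tapply(b$target_end, locus, max)
    best <- which.max(score)
    runner <- if (length(score) > 1) max(score[-best]) else 0
    placed <- score[best] >= min_unique_margin * runner
    data.frame(scaffold = b$query_chrom[1],
               z_start = if (placed) st[best] else NA_real_,
               z_end = if (placed) en[best] else NA_real_,
               score = score[best], placed = placed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(is.na(out$z_start), out$z_start), ]
  rownames(out) <- NULL
  out
}

#' Windowed W/Z divergence along Z
#'
#' Per Z window, divergence = 1 - sum(matches) / sum(aligned columns)
#' over the block portions overlapping the window; blocks are
#' apportioned pro rata by overlap length.  Windows with fewer than
#' `min_aligned` aligned bases are missing.
#'
#' @param blocks [alignment_blocks()] with Z as target.
#' @param z_length Z chromosome length (bp).
#' @param window_size window width (default 10 kb).
#' @param min_aligned minimum aligned bases per window.
#' @return list: `track` (a [window_track()] of divergence),
#'   `scaffold_of` (dominant query scaffold per window or NA).
#' @export
windowed_divergence <- function(blocks, z_length, window_size = 10000,
                                min_aligned = 1000) {
  n_win <- ceiling(z_length / window_size)
  aligned <- matches <- numeric(n_win)
  contrib <- vector("list", n_win)
  for (i in seq_len(nrow(blocks))) {
    bs <- blocks$target_start[i]; be <- blocks$target_end[i]
    w0 <- floor(bs / window_size); w1 <- floor((be - 1) / window_size)
    for (w in w0:w1) {
      ov <- min(be, (w + 1) * window_size) - max(bs, w * window_size)
      frac <- ov / (be - bs)
      aligned[w + 1] <- aligned[w + 1] + frac * blocks$aln_len[i]
      matches[w + 1] <- matches[w + 1] + frac * blocks$matches[i]
      contrib[[w + 1]] <- c(contrib[[w + 1]],
                            stats::setNames(frac * blocks$aln_len[i],
                                            blocks$query_chrom[i]))
    }
  }
  div <- ifelse(aligned >= min_aligned, 1 - matches / aligned, NA_real_)
  scaffold_of <- vapply(seq_len(n_win), function(w) {
    if (is.na(div[w]) || is.null(contrib[[w]])) return(NA_character_)
    s <- tapply(contrib[[w]], names(contrib[[w]]), sum)
    names(s)[which.max(s)]
  }, "")
  list(track = window_track("Z", window_size, div,
                            chrom_length = z_length),
       scaffold_of = scaffold_of)
}

# exact least-squares k-segmentation of a numeric series by dynamic
# programming; returns boundaries (last index of each segment) and RSS
.segment_dp <- function(v, k, min_seg = 1L) {
  n <- length(v)
  cs <- cumsum(v); cs2 <- cumsum(v^2)
  segcost <- function(i, j) {          # cost of v[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    q <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    q - s^2 / (j - i + 1)
  }
  cost <- matrix(Inf, k, n)            # cost[m, j]: first j pts, m segs
  back <- matrix(0L, k, n)
  for (j in seq_len(n)) if (j >= min_seg) cost[1, j] <- segcost(1, j)
  if (k > 1) for (m in 2:k) {
    for (j in seq_len(n)) {
      if (j < m * min_seg) next
      t <- ((m - 1) * min_seg):(j - min_seg)   # last index of m-1 segs
      s <- cs[j] - cs[t]
      q <- cs2[j] - cs2[t]
      cand <- cost[m - 1, t] + q - s^2 / (j - t)
      best <- which.min(cand)
      cost[m, j] <- cand[best]
      back[m, j] <- t[best]
    }
  }
  if (!is.finite(cost[k, n])) return(NULL)
  bounds <- integer(k)
  j <- n
  for (m in k:1) { bounds[m] <- j; j <- back[m, j] }
  list(bounds = bounds, rss = cost[k, n])
}

#' Segment a divergence track into evolutionary strata
#'
#' Optimal least-squares k-segmentation of the non-missing divergence
#' series by dynamic programming; `k = "auto"` selects the number of
#' strata in `1..k_max` by BIC (Gaussian likelihood, 2k free
#' parameters).  Strata are indexed by descending mean divergence
#' (S0 = oldest/most diverged).
#'
#' @param track a [window_track()] of per-window divergence (PAR
#'   windows, with no W alignment, are missing and excluded).
#' @param k number of strata, or `"auto"`.
#' @param min_seg_windows minimum non-missing windows per stratum.
#' @param k_max largest k tried when `k = "auto"`.
#' @param scaffold_of optional per-window scaffold names; when given,
#'   per-scaffold stratum assignment (majority of its windows) is
#'   returned.
#' @param prune with `k = "auto"`, merge adjacent segments whose split
#'   gain is not significant against a permutation null (circular
#'   binary segmentation-style changepoint pruning); guards against
#'   BIC over-selection.
#' @param prune_alpha significance level of the pruning test.
#' @return list: `strata` (data.frame name, start, end (bp),
#'   mean_divergence, n_windows, in positional order with age-rank
#'   names), `k`, `rss`, `bic`, and `scaffold_assignment` when
#'   requested.
#' @export
segment_strata <- function(track, k = "auto", min_seg_windows = 5L,
                           k_max = 6L, scaffold_of = NULL,
                           prune = TRUE, prune_alpha = 0.01) {
  keep <- which(!is.na(track$values))
  v <- track$values[keep]
  n <- length(v)
  fit_k <- function(kk) .segment_dp(v, kk, min_seg_windows)
  if (identical(k, "auto")) {
    fits <- list(); bics <- rep(Inf, k_max)
    for (kk in seq_len(k_max)) {
      f <- fit_k(kk)
      if (is.null(f)) break
      sigma2 <- max(f$rss / n, 1e-12)
      bics[kk] <- n * log(sigma2) + 2 * kk * log(n)
      fits[[kk]] <- f
    }
    if (!length(fits)) stop("series too short for any segmentation")
    k <- which.min(bics)
    fit <- fits[[k]]
    bic <- bics[k]
    if (prune && k > 1) {
      fit <- .prune_boundaries(v, fit$bounds, min_seg_windows,
                               prune_alpha)
      k <- length(fit$bounds)
    }
  } else {
    if (n < k * min_seg_windows) stop("infeasible k for series length")
    fit <- fit_k(k)
    if (is.null(fit)) stop("infeasible k for series length")
    sigma2 <- max(fit$rss / n, 1e-12)
    bic <- n * log(sigma2) + 2 * k * log(n)
  }
  seg_start <- c(1L, utils::head(fit$bounds, -1) + 1L)
  ws <- track$window_size
  strata <- data.frame(
    start = (keep[seg_start] - 1) * ws,
    end = pmin(keep[fit$bounds] * ws, track$chrom_length),
    mean_divergence = vapply(seq_len(k), function(m)
      mean(v[seg_start[m]:fit$bounds[m]]), numeric(1)),
    n_windows = fit$bounds - seg_start + 1L)
  age_rank <- rank(-strata$mean_divergence, ties.method = "first")
  strata$name <- paste0("S", age_rank - 1L)
  strata <- strata[, c("name", "start", "end", "mean_divergence",
                       "n_windows")]
  out <- list(strata = strata, k = k, rss = fit$rss, bic = bic)
  if (!is.null(scaffold_of)) {
    win_seg <- rep(seq_len(k), fit$bounds - seg_start + 1L)
    lab <- strata$name[win_seg]
    sc <- scaffold_of[keep]
    ok <- !is.na(sc)
    assign <- vapply(split(lab[ok], sc[ok]), function(x)
      names(which.max(table(x))), "")
    out$scaffold_assignment <- assign
  }
  out
}

# merge adjacent segments whose boundary is not supported: the
# observed RSS gain of keeping the two segments separate is compared
# with the null distribution of the best single-split gain on permuted
# values of the merged segment (CBS-style pruning).  Deterministic:
# runs under an isolated, fixed RNG state.
.prune_boundaries <- function(v, bounds, min_seg, alpha,
                              n_perm = 999L) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(derive_seed(length(v), "prune_boundaries"))
  sse <- function(x) sum((x - mean(x))^2)
  best_split_gain <- function(x) {
    m <- length(x)
    if (m < 2 * min_seg) return(0)
    cs <- cumsum(x); cs2 <- cumsum(x^2)
    t <- min_seg:(m - min_seg)
    two <- (cs2[t] - cs[t]^2 / t) +
      ((cs2[m] - cs2[t]) - (cs[m] - cs[t])^2 / (m - t))
    sse(x) - min(two)
  }
  repeat {
    k <- length(bounds)
    if (k == 1) break
    starts <- c(1L, utils::head(bounds, -1) + 1L)
    pvals <- numeric(k - 1)
    for (j in seq_len(k - 1)) {
      merged <- v[starts[j]:bounds[j + 1]]
      gain <- sse(merged) -
        (sse(v[starts[j]:bounds[j]]) +
           sse(v[starts[j + 1]:bounds[j + 1]]))
      null <- vapply(seq_len(n_perm), function(b)
        best_split_gain(sample(merged)), numeric(1))
      pvals[j] <- (1 + sum(null >= gain)) / (1 + n_perm)
    }
    worst <- which.max(pvals)
    if (pvals[worst] <= alpha) break
    bounds <- bounds[-worst]
  }
  starts <- c(1L, utils::head(bounds, -1) + 1L)
  rss <- sum(vapply(seq_along(bounds), function(m)
    sse(v[starts[m]:bounds[m]]), numeric(1)))
  list(bounds = bounds, rss = rss)
}

# brute-force exhaustive segmentation (oracle for tests)
#' Exhaustive least-squares segmentation (reference implementation)
#'
#' Enumerates every placement of `k - 1` boundaries; only feasible for
#' short series.  Used as an independent oracle for the dynamic
#' program.
#'
#' @param v numeric series (no missing values).
#' @param k number of segments.
#' @param min_seg minimum segment length.
#' @return list with `bounds` and `rss`, as [segment_strata()]'s DP.
#' @export
segment_exhaustive <- function(v, k, min_seg = 1L) {
  n <- length(v)
  sse <- function(x) sum((x - mean(x))^2)
  best <- NULL; best_rss <- Inf
  if (k == 1) return(list(bounds = n, rss = sse(v)))
  combos <- utils::combn(n - 1, k - 1)
  for (ci in seq_len(ncol(combos))) {
    b <- c(combos[, ci], n)
    lens <- diff(c(0, b))
    if (any(lens < min_seg)) next
    rss <- sum(vapply(seq_len(k), function(m)
      sse(v[(c(0, b)[m] + 1):b[m]]), numeric(1)))
    if (rss < best_rss) { best_rss <- rss; best <- b }
  }
  list(bounds = best, rss = best_rss)
}
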