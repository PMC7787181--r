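# Classify scaffolds as Z / W / autosomal from sexed depth tracks,
# locate the PAR boundary on Z, and compute sex-bias and
# tissue-specificity expression statistics.
#
# Classification thresholds follow the standard coverage criteria:
# M/F depth ratio in [1.5, 2.5] -> Z-linked; depth ratio or coverage
# ratio in [0, 0.25] -> W-linked; minimum 80% read coverage in both
# sexes required for any assignment.

#' Normalize a depth track by the genome-wide per-bp median
#'
#' @param track a [window_track()] of raw window depths.
#' @param genome_median_per_bp positive genome-wide median depth per bp.
#' @return the track with each value divided by the median; missing
#'   windows propagated.
#' @export
normalize_depth <- function(track, genome_median_per_bp) {
  if (!is.numeric(genome_median_per_bp) || genome_median_per_bp <= 0)
    stop("genome median must be positive")
  track$values <- track$values / genome_median_per_bp
  track
}

#' Classify a scaffold's sex linkage from normalized M and F depth
#'
#' Ratios are computed over mutually covered windows only.  A window
#' counts as covered when its normalized depth exceeds
#' `covered_min_depth`.
#'
#' @param normM,normF normalized [window_track()]s for the male and
#'   female on the same scaffold and window grid.
#' @param z_range M/F depth-ratio interval assigned Z.
#' @param w_max upper bound of the W band for both the depth ratio and
#'   the coverage ratio (joined by OR).
#' @param coverage_floor minimum covered fraction required in both sexes
#'   for any call; otherwise `unassigned`.
#' @param covered_min_depth normalized depth above which a window counts
#'   as covered.
#' @return one-row data.frame: scaffold, label in
#'   `{Z, W, autosomal, unassigned}`, mf_depth_ratio, mf_coverage_ratio,
#'   covered_fraction_M, covered_fraction_F.
#' @export
classify_sex_linkage <- function(normM, normF, z_range = c(1.5, 2.5),
                                 w_max = 0.25, coverage_floor = 0.80,
                                 covered_min_depth = 0.05) {
  if (normM$chrom != normF$chrom ||
      normM$window_size != normF$window_size ||
      length(normM$values) != length(normF$values))
    stop("tracks must share scaffold and window grid")
  m <- normM$values; f <- normF$values
  def <- !is.na(m) & !is.na(f)
  cfm <- mean(m[def] > covered_min_depth)
  cff <- mean(f[def] > covered_min_depth)
  cov_ratio <- if (cff == 0) Inf else cfm / cff
  both <- def & m > covered_min_depth & f > covered_min_depth
  mean_m <- mean(m[def])
  mean_f <- mean(f[def])
  depth_ratio <- if (mean_f == 0) {
    if (mean_m > 0) Inf else NA_real_
  } else mean_m / mean_f
  # W is callable below the coverage floor: absence of male reads is
  # the signal itself, so the W test (depth OR coverage ratio) precedes
  # the coverage-floor gate
  label <- if ((!is.na(depth_ratio) && depth_ratio <= w_max) ||
               cov_ratio <= w_max) {
    "W"
  } else if (min(cfm, cff) < coverage_floor) {
    "unassigned"
  } else if (!is.na(depth_ratio) && depth_ratio >= z_range[1] &&
             depth_ratio <= z_range[2]) {
    "Z"
  } else {
    "autosomal"
  }
  data.frame(scaffold = normM$chrom, label = label,
             mf_depth_ratio = depth_ratio, mf_coverage_ratio = cov_ratio,
             covered_fraction_M = cfm, covered_fraction_F = cff,
             n_windows_used = sum(both), stringsAsFactors = FALSE)
}

#' Classify many scaffolds at once
#'
#' @param tracksM,tracksF named lists of normalized [window_track()]s.
#' @param ... passed to [classify_sex_linkage()].
#' @return data.frame with one row per scaffold.
#' @export
classify_scaffolds <- function(tracksM, tracksF, ...) {
  stopifnot(identical(names(tracksM), names(tracksF)))
  do.call(rbind, lapply(names(tracksM), function(nm)
    classify_sex_linkage(tracksM[[nm]], tracksF[[nm]], ...)))
}

#' Detect the pseudoautosomal region on Z from the M/F ratio track
#'
#' Fits a two-segment least-squares changepoint to the per-window M/F
#' depth-ratio series, trying the PAR at either terminus, and accepts
#' the fit whose PAR-side mean lies in `tol_par` and SDR-side mean in
#' `tol_sdr`.
#'
#' @param ratio_track [window_track()] of per-window M/F normalized
#'   depth ratios along Z.
#' @param tol_par acceptance interval for the PAR segment mean
#'   (diploid in both sexes, ratio near 1).
#' @param tol_sdr acceptance interval for the SDR segment mean (Z is
#'   hemizygous in females, ratio near 2).
#' @return list: `boundary` (bp), `par_interval` (data.frame),
#'   `mean_ratio_par`, `mean_ratio_sdr`, `side` ("left"/"right"); or
#'   `NULL` when no changepoint satisfies the tolerance bands.
#' @export
detect_par <- function(ratio_track, tol_par = c(0.75, 1.25),
                       tol_sdr = c(1.5, 2.5)) {
  x <- ratio_track$values
  keep <- which(!is.na(x) & x > 0)
  if (length(keep) < 4) stop("track shorter than 4 windows")
  # fit on the log scale: depth-ratio noise is multiplicative and
  # right-skewed, so least squares on raw ratios is outlier-driven
  v <- log2(x[keep])
  n <- length(v)
  cs <- cumsum(v); cs2 <- cumsum(v^2)
  # SSE of v[1..b] and v[(b+1)..n] for every split b
  b <- seq_len(n - 1)
  s1 <- cs[b]; s2 <- cs[n] - cs[b]
  q1 <- cs2[b]; q2 <- cs2[n] - cs2[b]
  sse <- (q1 - s1^2 / b) + (q2 - s2^2 / (n - b))
  best <- which.min(sse)
  # geometric segment means, reported on the ratio scale
  mean_left <- 2^(s1[best] / best)
  mean_right <- 2^(s2[best] / (n - best))
  in_band <- function(m, band) m >= band[1] & m <= band[2]
  side <- if (in_band(mean_left, tol_par) && in_band(mean_right, tol_sdr))
    "left"
  else if (in_band(mean_right, tol_par) && in_band(mean_left, tol_sdr))
    "right"
  else return(NULL)
  ws <- ratio_track$window_size
  len <- ratio_track$chrom_length
  if (side == "left") {
    boundary <- keep[best] * ws          # end of window keep[best]
    par_iv <- data.frame(chrom = ratio_track$chrom, start = 0,
                         end = min(boundary, len))
    mp <- mean_left; ms <- mean_right
  } else {
    boundary <- (keep[best + 1] - 1) * ws  # start of window keep[best+1]
    par_iv <- data.frame(chrom = ratio_track$chrom, start = boundary,
                         end = len)
    mp <- mean_right; ms <- mean_left
  }
  list(boundary = boundary, par_interval = par_iv,
       mean_ratio_par = mp, mean_ratio_sdr = ms, side = side)
}

#' Per-gene male/female expression ratio and per-chromosome medians
#'
#' @param expr genes x samples expression matrix (normalized).
#' @param sex_labels character vector `"M"`/`"F"` per sample column.
#' @param gene_chrom optional chromosome per gene for the per-chromosome
#'   summary.
#' @param pseudocount added to both sex means before the ratio.
#' @return list: `ratio` (per gene), `by_chrom` (named median ratios,
#'   when `gene_chrom` given).
#' @export
mf_expression_ratio <- function(expr, sex_labels, gene_chrom = NULL,
                                pseudocount = 0.1) {
  if (!all(c("M", "F") %in% sex_labels))
    stop("need at least one sample per sex")
  mM <- rowMeans(expr[, sex_labels == "M", drop = FALSE])
  mF <- rowMeans(expr[, sex_labels == "F", drop = FALSE])
  ratio <- (mM + pseudocount) / (mF + pseudocount)
  by_chrom <- NULL
  if (!is.null(gene_chrom))
    by_chrom <- tapply(ratio, gene_chrom, stats::median)
  list(ratio = ratio, by_chrom = by_chrom)
}

#' Tissue-specificity index tau
#'
#' `tau = sum(1 - x_i / max(x)) / (n - 1)`: 0 for uniform expression
#' across tissues, 1 for single-tissue expression.
#'
#' @param tissue_medians non-negative vector of per-tissue median
#'   expression, length >= 2.
#' @return tau in \[0, 1\].
#' @export
tau <- function(tissue_medians) {
  x <- tissue_medians
  if (length(x) < 2) stop("need at least 2 tissues")
  if (any(x < 0)) stop("tissue medians must be non-negative")
  if (max(x) == 0) stop("tau undefined for an all-zero vector")
  sum(1 - x / max(x)) / (length(x) - 1)
}
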