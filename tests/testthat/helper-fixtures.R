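# shared fixtures, built in code

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_dna <- function(seq, rate) {
  v <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(v)) < rate)
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))
  v[hit] <- vapply(v[hit], function(b) sample(alt[[b]], 1L), "")
  paste(v, collapse = "")
}

# one shared default simulated genome, built once per test run
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_genome(sim_params(seed = 11L))
    cache
  }
})

# minimal truth stub for Hi-C simulation with chosen TAD/compartment
# structure on one chromosome
hic_truth <- function(n_bins, tad_ends, comp_labels = NULL,
                      bin_size = 10000, chrom = "c1") {
  if (is.null(comp_labels)) comp_labels <- rep("A", n_bins)
  tads <- data.frame(start_bin = c(0L, utils::head(tad_ends, -1)),
                     end_bin = tad_ends)
  truth <- list(chrom_lengths = stats::setNames(n_bins * bin_size, chrom),
                tads = stats::setNames(list(tads), chrom),
                compartments = stats::setNames(list(comp_labels), chrom))
  truth
}

# a small information-rich PWM (consensus TGCACA) for motif-scan tests
test_pwm <- function() {
  cons <- c("T", "G", "C", "A", "C", "A")
  pwm <- matrix(0.04, 4, length(cons),
                dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(cons)) pwm[cons[j], j] <- 0.88
  pwm
}

# brute-force PWM scorer: independent oracle for scan_pwm
brute_pwm_hits <- function(seq, pwm, background = rep(0.25, 4),
                           threshold = 0.8) {
  if (any(pwm == 0)) {
    pwm <- pwm + 1e-3
    pwm <- sweep(pwm, 2, colSums(pwm), "/")
  }
  lo <- log2(pwm / background)
  L <- ncol(lo)
  cutoff <- threshold * sum(apply(lo, 2, max))
  bases <- c("A", "C", "G", "T")
  score_at <- function(s, p) {
    tot <- 0
    for (j in seq_len(L)) {
      b <- substr(s, p + j - 1, p + j - 1)
      tot <- tot + if (b %in% bases) lo[b, j] else 0
    }
    tot
  }
  out <- list()
  n <- nchar(seq)
  rc <- revcomp(seq)
  for (p in seq_len(n - L + 1)) {
    sf <- score_at(seq, p)
    if (sf >= cutoff)
      out[[length(out) + 1]] <- data.frame(start = p - 1L, strand = "+",
                                           score = sf)
    sr <- score_at(rc, p)
    if (sr >= cutoff)
      out[[length(out) + 1]] <- data.frame(start = n - L + 1L - p,
                                           strand = "-", score = sr)
  }
  if (!length(out))
    return(data.frame(start = integer(), strand = character(),
                      score = numeric()))
  out <- do.call(rbind, out)
  out <- out[order(out$start), ]
  rownames(out) <- NULL
  out
}
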