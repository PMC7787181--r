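test_that("simulate_genome is deterministic and truth echoes config", {
  p <- sim_params(seed = 4)
  a <- simulate_genome(p)
  b <- simulate_genome(p)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$truth, b$truth)
  d <- simulate_genome(sim_params(seed = 5))
  expect_false(identical(a$sequences, d$sequences))
  expect_equal(a$truth$par_interval$start, 0)
  expect_equal(a$truth$par_interval$end, 1e5)
  # strata tile the SDR, disjoint, oldest first
  st <- a$truth$strata
  expect_equal(st$start[-1], head(st$end, -1))
  expect_equal(st$divergence, sort(st$divergence, decreasing = TRUE))
})

test_that("planted W stratum divergence matches empirical mismatch rate", {
  sim <- shared_sim()
  tr <- sim$truth
  zs <- sim$sequences[["Z"]]
  ws <- sim$sequences[["W"]]
  for (i in c(1, nrow(tr$w_scaffolds))) {
    w <- tr$w_scaffolds[i, ]
    src <- strsplit(substr(zs, w$z_start + 1, w$z_end), "")[[1]]
    der <- strsplit(substr(ws, w$w_offset + 1, w$w_offset + w$length),
                    "")[[1]]
    mism <- mean(src != der)
    expect_lt(abs(mism - w$divergence), 0.01)
  }
})

test_that("planted palindrome arms are reverse complements in sequence", {
  sim <- shared_sim()
  ws <- sim$sequences[["W"]]
  for (i in seq_len(nrow(sim$truth$palindromes))) {
    p <- sim$truth$palindromes[i, ]
    a1 <- substr(ws, p$arm1_start + 1, p$arm1_end)
    a2 <- substr(ws, p$arm2_start + 1, p$arm2_end)
    expect_identical(a2, revcomp(a1))
  }
})

test_that("planted arrays are present verbatim", {
  sim <- shared_sim()
  p <- sim_params(seed = 11L)
  cen <- sim$truth$centromeres[1, ]
  expect_identical(substr(sim$sequences[[cen$chrom]], cen$start + 1,
                          cen$start + 190), p$monomer)
  tel <- sim$truth$telomeres[1, ]
  expect_identical(substr(sim$sequences[[tel$chrom]], tel$start + 1,
                          tel$start + 6), p$telomere_motif)
})

test_that("simulate_depth honors copy number and dispersion", {
  sim <- shared_sim()
  p <- sim_params(seed = 21)
  trW <- simulate_depth(sim$truth, p, "M", "W")
  expect_true(all(trW$values == 0))
  # law of large numbers on an autosome: 400 windows of A1
  trA <- simulate_depth(sim$truth, p, "M", "A1", window_size = 5000)
  expect_lt(abs(mean(trA$values) - 30) / 30, 0.05)
  # Z SDR M:F ratio near 2
  m <- simulate_depth(sim$truth, p, "M", "Z")
  f <- simulate_depth(sim$truth, p, "F", "Z")
  sdr <- track_starts(m) >= sim$truth$par_interval$end
  r <- mean(m$values[sdr]) / mean(f$values[sdr])
  expect_gt(r, 1.8); expect_lt(r, 2.2)
  # PAR windows diploid in both sexes
  par <- !sdr
  rp <- mean(m$values[par]) / mean(f$values[par])
  expect_gt(rp, 0.85); expect_lt(rp, 1.15)
  expect_error(simulate_depth(sim$truth, p, "M", "chrUn"), "unknown")
})

test_that("simulate_hic is symmetric, deterministic, follows decay", {
  p <- sim_params(seed = 6, tad_enrichment = 1 + 1e-9,
                  compartment_strength = 0)
  truth <- hic_truth(120, tad_ends = c(60L, 120L))
  m1 <- simulate_hic(truth, p, "c1")
  expect_identical(m1$counts, t(m1$counts))
  m2 <- simulate_hic(truth, p, "c1")
  expect_identical(m1$counts, m2$counts)
  # log-log regression of mean count vs distance recovers the exponent
  d <- abs(outer(1:120, 1:120, "-"))
  md <- tapply(m1$counts, d, mean)
  dist <- as.numeric(names(md))
  use <- dist >= 1 & dist <= 40
  fit <- stats::lm(log(md[use]) ~ log(dist[use] + 1))
  expect_lt(abs(unname(fit$coefficients[2]) - (-1)), 0.1)
})

test_that("simulated alignments carry planted inversions and divergence", {
  sim <- shared_sim()
  p <- sim_params(seed = 11L)
  aln <- simulate_alignments(sim$truth, p)
  # no inversions planted outside A1: all their blocks are "+"
  other <- aln$focal_vs_b[aln$focal_vs_b$query_chrom != "A1", ]
  expect_true(all(other$strand == "+"))
  # focal-lineage inversions flip in both comparisons, B-lineage only
  # in focal-vs-B
  inv <- sim$truth$inversions
  for (i in seq_len(nrow(inv))) {
    inb <- aln$focal_vs_b$query_chrom == "A1" &
      aln$focal_vs_b$query_start >= inv$start[i] &
      aln$focal_vs_b$query_end <= inv$end[i]
    expect_true(all(aln$focal_vs_b$strand[inb] == "-"))
    ino <- aln$focal_vs_outgroup$query_chrom == "A1" &
      aln$focal_vs_outgroup$query_start >= inv$start[i] &
      aln$focal_vs_outgroup$query_end <= inv$end[i]
    expected <- if (inv$lineage[i] == "focal") "-" else "+"
    expect_true(all(aln$focal_vs_outgroup$strand[ino] == expected))
  }
  # W block identity tracks the stratum divergence
  w0 <- sim$truth$w_scaffolds$name[1]
  div0 <- sim$truth$w_scaffolds$divergence[1]
  wb <- aln$w_vs_z[aln$w_vs_z$query_chrom == w0, ]
  expect_lt(abs(mean(1 - wb$identity) - div0), 0.02)
})

test_that("no planted inversions gives all forward blocks", {
  p <- sim_params(seed = 8)
  sim <- simulate_genome(p, inversion_sizes = numeric(0),
                         inversion_lineages = character(0))
  aln <- simulate_alignments(sim$truth, p)
  expect_true(all(aln$focal_vs_b$strand == "+"))
  expect_true(all(aln$focal_vs_outgroup$strand == "+"))
})

test_that("simulate_expression plants TAU classes and Z male bias", {
  sim <- shared_sim()
  p <- sim_params(seed = 31)
  ex <- simulate_expression(sim$truth, p, n_tissues = 5, n_per_sex = 3)
  med_by_tissue <- function(g) {
    vapply(unique(ex$samples$tissue), function(t)
      stats::median(ex$expr[g, ex$samples$tissue == t]), numeric(1))
  }
  hk <- which(ex$genes$class == "housekeeping")
  taus_hk <- vapply(hk, function(g) tau(med_by_tissue(g)), numeric(1))
  expect_lt(stats::median(taus_hk), 0.2)
  ts <- which(ex$genes$class == "tissue_specific")
  taus_ts <- vapply(ts, function(g) tau(med_by_tissue(g)), numeric(1))
  expect_true(all(taus_ts > 0.95))
  mf <- mf_expression_ratio(ex$expr, ex$samples$sex, ex$genes$chrom)
  expect_gt(mf$by_chrom[["Z"]], 1.8)
  expect_lt(mf$by_chrom[["Z"]], 2.2)
  expect_gt(mf$by_chrom[["A1"]], 0.9)
  expect_lt(mf$by_chrom[["A1"]], 1.1)
  expect_error(simulate_expression(sim$truth, p, n_tissues = 1), "2")
})

test_that("derive_seed is stable, label-sensitive and in range", {
  expect_identical(derive_seed(1, "a"), derive_seed(1, "a"))
  expect_false(derive_seed(1, "a") == derive_seed(1, "b"))
  expect_false(derive_seed(1, "a") == derive_seed(2, "a"))
  s <- vapply(1:50, function(i) derive_seed(i, "stage"), integer(1))
  expect_true(all(s >= 1 & s < 2^31))
})
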