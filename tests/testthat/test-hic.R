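test_that("ice_normalize equalizes row sums and masks empty bins", {
  m <- contact_matrix("c", 10, matrix(c(2, 1, 1, 2), 2))
  bal <- ice_normalize(m)
  rs <- rowSums(bal$matrix$counts)
  expect_lt(diff(range(rs)) / mean(rs), 1e-5)
  # symmetric 2x2 with equal diagonal: biases equal by symmetry
  expect_equal(bal$bias[1], bal$bias[2], tolerance = 1e-6)
  # already-balanced matrix unchanged up to scale
  u <- matrix(1, 4, 4)
  balu <- ice_normalize(contact_matrix("c", 10, u))
  expect_equal(balu$matrix$counts / balu$matrix$counts[1, 1], u)
  # all-zero row is masked, remainder balanced
  z <- matrix(runif(25, 1, 3), 5); z <- z + t(z); z[3, ] <- 0; z[, 3] <- 0
  balz <- ice_normalize(contact_matrix("c", 10, z))
  expect_true(balz$matrix$mask[3])
  expect_true(is.na(balz$bias[3]))
  rs <- rowSums(balz$matrix$counts)[-3]
  expect_lt(stats::sd(rs) / mean(rs), 1e-5)
  expect_error(ice_normalize(contact_matrix("c", 10, matrix(0, 3, 3))),
               "no unmasked")
})

test_that("balancing twice is a no-op and scaling invariance holds", {
  set.seed(5)
  m0 <- matrix(rpois(400, 20), 20); m0 <- m0 + t(m0)
  b1 <- ice_normalize(contact_matrix("c", 10, m0))
  b2 <- ice_normalize(b1$matrix)
  expect_equal(b2$matrix$counts, b1$matrix$counts, tolerance = 1e-4)
  # insulation invariant to positive scaling of the matrix
  i1 <- insulation_score(b1$matrix, 3)
  scaled <- contact_matrix("c", 10, b1$matrix$counts * 7.3)
  i2 <- insulation_score(scaled, 3)
  expect_equal(i1$values, i2$values, tolerance = 1e-12)
})

test_that("insulation score is zero on a uniform matrix", {
  m <- contact_matrix("c", 10, matrix(3, 30, 30))
  ins <- insulation_score(m, 5)
  def <- !is.na(ins$values)
  expect_equal(sum(def), 30 - 10)
  expect_true(all(abs(ins$values[def]) < 1e-12))
  expect_error(insulation_score(m, 20), "window_bins")
})

test_that("two dense blocks give a single minimum at the junction", {
  n <- 40
  m <- matrix(0, n, n)
  m[1:20, 1:20] <- 5; m[21:40, 21:40] <- 5
  ins <- insulation_score(contact_matrix("c", 10, m), 5)
  v <- ins$values
  expect_equal(which.min(v), 20, tolerance = 1)
  b <- call_tad_boundaries(ins, min_strength = 0.5)
  expect_equal(nrow(b), 1)
})

test_that("call_tad_boundaries handles minima, plateaus, monotone", {
  tr <- window_track("c", 10, c(0, -1, 0))
  b <- call_tad_boundaries(tr, min_strength = 0.5)
  expect_equal(b$bin, 1)
  expect_equal(b$strength, 1)
  # monotone: nothing
  expect_equal(nrow(call_tad_boundaries(window_track("c", 10, 1:10 / 10),
                                        min_strength = 0)), 0)
  # plateau resolves to the central bin
  tr2 <- window_track("c", 10, c(1, 0, 0, 0, 1))
  b2 <- call_tad_boundaries(tr2, min_strength = 0.5)
  expect_equal(b2$bin, 2)
  # sub-threshold strength dropped
  tr3 <- window_track("c", 10, c(0, -0.05, 0))
  expect_equal(nrow(call_tad_boundaries(tr3, min_strength = 0.1)), 0)
})

test_that("planted TADs are recovered with F1 >= 0.9", {
  p <- sim_params(seed = 19, compartment_strength = 0)
  ends <- c(30L, 55L, 90L, 120L, 150L, 180L)
  truth <- hic_truth(180, ends)
  m <- simulate_hic(truth, p, "c1")
  bal <- ice_normalize(m)
  ins <- insulation_score(bal$matrix, 10)
  b <- call_tad_boundaries(ins)
  f1 <- boundary_f1(b$bin, utils::head(ends, -1), tol = 1)
  expect_gte(f1, 0.9)
})

test_that("compartment eigenvector recovers a checkerboard", {
  # small deterministic block checkerboard: eigen oracle (strict
  # single-bin alternation would make every diagonal constant and the
  # correlation matrix degenerate)
  lab <- rep(rep(c("A", "B"), 2), c(6, 5, 4, 5))
  base <- ifelse(outer(lab, lab, "=="), 2, 0.5)
  m <- contact_matrix("c", 10, base)
  orient <- window_track("c", 10, ifelse(lab == "A", 0.6, 0.4))
  cp <- ab_compartments(m, orient)
  expect_false(cp$degenerate)
  expect_identical(cp$label, lab)
  # sign fixed by eigen-decomposition oracle on the same matrix
  nk <- 20
  d <- abs(outer(seq_len(nk), seq_len(nk), "-"))
  expd <- tapply(base, d, mean)
  oe <- base / matrix(expd[as.character(d)], nk, nk)
  ev <- eigen(stats::cor(oe))$vectors[, 1]
  expect_gt(abs(stats::cor(ev, cp$value)), 0.999)
  # flipping the orientation track flips all labels
  flip <- window_track("c", 10, ifelse(lab == "A", 0.4, 0.6))
  cp2 <- ab_compartments(m, flip)
  expect_identical(cp2$label, ifelse(lab == "A", "B", "A"))
  # scaling invariance
  cp3 <- ab_compartments(contact_matrix("c", 10, base * 11), orient)
  expect_identical(cp3$label, cp$label)
  # uniform matrix is degenerate
  u <- ab_compartments(contact_matrix("c", 10, matrix(1, 15, 15)),
                       window_track("c", 10, runif(15)))
  expect_true(u$degenerate)
})

test_that("scan_pwm equals the brute-force scorer and strand symmetry", {
  pwm <- test_pwm()
  set.seed(23)
  s <- paste0(random_dna(300), "TGCACA", random_dna(200))
  hits <- scan_pwm(s, pwm, threshold = 0.9)
  expect_true(any(hits$start == 300 & hits$strand == "+"))
  # oracle equivalence on a random sequence at two thresholds
  for (th in c(0.8, 0.95)) {
    got <- scan_pwm(s, pwm, threshold = th)
    want <- brute_pwm_hits(s, pwm, threshold = th)
    expect_equal(got, want, ignore_attr = TRUE)
  }
  # reverse complement flips strands and mirrors positions
  rc_hits <- scan_pwm(revcomp(s), pwm, threshold = 0.9)
  L <- ncol(pwm)
  mapped <- sort(nchar(s) - L - rc_hits$start)
  expect_equal(mapped, sort(hits$start))
  expect_error(scan_pwm(s, pwm[1:3, ]), "4 rows")
})

test_that("N bases score as background in scan_pwm", {
  pwm <- test_pwm()
  hits <- scan_pwm("NNTGCACANN", pwm, threshold = 0.7)
  expect_true(any(hits$start == 2 & hits$strand == "+"))
})

test_that("convergent_pairs counts plus-before-minus pairs", {
  h <- data.frame(start = c(1000, 50000), strand = c("+", "-"))
  expect_equal(nrow(convergent_pairs(h, 1e5)), 1)
  h2 <- data.frame(start = c(1000, 50000), strand = c("-", "+"))
  expect_equal(nrow(convergent_pairs(h2, 1e5)), 0)
  # k plus-hits upstream of m minus-hits -> k*m pairs
  h3 <- data.frame(start = c(1:3 * 100, 4:8 * 100),
                   strand = rep(c("+", "-"), c(3, 5)))
  expect_equal(nrow(convergent_pairs(h3, 1e4)), 15)
  expect_equal(nrow(convergent_pairs(h3, 150)), 1)  # span filter
})

test_that("annotate_boundaries flags features and tabulates classes", {
  b <- data.frame(bin = c(10, 20), start = c(1e5, 2e5),
                  end = c(1.1e5, 2.1e5))
  ann <- annotate_boundaries(b, ctcf_positions = 1.02e5, flank = 1e4)
  expect_identical(unname(ann$flags$ctcf), c(TRUE, FALSE))
  expect_false(any(ann$flags$housekeeping))
  expect_equal(unname(ann$class_counts[["100"]]), 1)
  expect_equal(unname(ann$class_counts[["000"]]), 1)
  # empty feature sets
  ann0 <- annotate_boundaries(b)
  expect_equal(unname(ann0$class_counts[["000"]]), 2)
})

test_that("CTCF sites planted at boundaries are enriched over random", {
  set.seed(77)
  bnd <- data.frame(bin = 1:20 * 10,
                    start = 1:20 * 1e5, end = 1:20 * 1e5 + 1e4)
  ctcf <- c(bnd$start[1:15] + 2000, runif(5, 0, 2.1e6))
  ann <- annotate_boundaries(bnd, ctcf_positions = ctcf, flank = 1e4)
  obs <- mean(ann$flags$ctcf)
  # permutation: random bins on the same chromosome
  null_frac <- vapply(1:200, function(i) {
    rb <- runif(20, 0, 2.1e6)
    rbd <- data.frame(start = rb, end = rb + 1e4)
    mean(annotate_boundaries(rbd, ctcf_positions = ctcf,
                             flank = 1e4)$flags$ctcf)
  }, numeric(1))
  p <- (1 + sum(null_frac >= obs)) / 201
  expect_lt(p, 0.05)
})

test_that("boundary_sharing projects through synteny and applies slack", {
  blocks <- alignment_blocks("a", 0, 1e6, "b", 0, 1e6, "+", 1e6, 1e6)
  ba <- data.frame(start = c(1e5, 5e5, 9e5))
  # identical boundary sets -> fraction 1
  sh <- boundary_sharing(ba, ba, blocks, slack_bins = 1,
                         bin_size = 1e4)
  expect_equal(sh$fraction, 1)
  # disjoint sets -> 0
  bb <- data.frame(start = c(2e5, 6e5))
  expect_equal(boundary_sharing(ba, bb, blocks, 1, 1e4)$fraction, 0)
  # shift by exactly one bin with slack 1 -> shared
  bb2 <- data.frame(start = ba$start + 1e4)
  expect_equal(boundary_sharing(ba, bb2, blocks, 1, 1e4)$fraction, 1)
  # reverse-strand projection mirrors coordinates
  rev_blocks <- alignment_blocks("a", 0, 1e6, "b", 0, 1e6, "-", 1e6, 1e6)
  shr <- boundary_sharing(data.frame(start = 1e5),
                          data.frame(start = 9e5), rev_blocks, 1, 1e4)
  expect_equal(shr$fraction, 1)
  # boundary in an unaligned gap is excluded from the denominator
  part <- alignment_blocks("a", 0, 4e5, "b", 0, 4e5, "+", 4e5, 4e5)
  shg <- boundary_sharing(ba, ba, part, 1, 1e4)
  expect_equal(shg$n_projectable, 1)
})
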