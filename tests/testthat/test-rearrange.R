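mk_blocks <- function(qs, qe, strand, ts = qs, te = qe) {
  alignment_blocks("q", qs, qe, "t", ts, te, strand,
                   round((qe - qs) * 0.98), qe - qs)
}

test_that("chain_synteny merges collinear blocks and splits on strand", {
  b <- mk_blocks(c(0, 6000, 12000), c(5000, 11000, 17000), "+")
  ch <- chain_synteny(b, max_gap = 5000)
  expect_equal(nrow(ch), 1)
  expect_equal(ch$n_blocks, 3)
  # +,-,+ -> three chains
  b2 <- mk_blocks(c(0, 6000, 12000), c(5000, 11000, 17000),
                  c("+", "-", "+"))
  expect_equal(nrow(chain_synteny(b2, max_gap = 5000)), 3)
  # gap larger than max_gap splits
  b3 <- mk_blocks(c(0, 60000), c(5000, 65000), "+")
  expect_equal(nrow(chain_synteny(b3, max_gap = 5000)), 2)
})

test_that("chaining is invariant to input block order", {
  set.seed(41)
  sim <- shared_sim()
  aln <- simulate_alignments(sim$truth, sim_params(seed = 11L))
  b <- aln$focal_vs_b[aln$focal_vs_b$query_chrom == "A1", ]
  ch1 <- chain_synteny(b)
  for (i in 1:5) {
    ch2 <- chain_synteny(b[sample(nrow(b)), ])
    expect_equal(ch2, ch1)
  }
})

test_that("call_inversions applies the length threshold", {
  b <- mk_blocks(c(0, 20000, 80000), c(15000, 70000, 100000),
                 c("+", "-", "+"),
                 ts = c(0, 20000, 80000), te = c(15000, 70000, 100000))
  # reversed middle chain of span 50 kb -> one inversion
  ch <- chain_synteny(b, max_gap = 1e5)
  inv <- call_inversions(ch, query_chrom = "q")
  expect_equal(nrow(inv), 1)
  expect_equal(inv$start, 20000)
  expect_equal(inv$end, 70000)
  # 5-kb reversed chain is below the 10-kb floor
  b2 <- mk_blocks(c(0, 20000, 30000), c(15000, 25000, 50000),
                  c("+", "-", "+"))
  expect_equal(nrow(call_inversions(chain_synteny(b2, max_gap = 1e5))), 0)
})

test_that("planted inversions are recovered and polarized", {
  sim <- shared_sim()
  p <- sim_params(seed = 11L)
  aln <- simulate_alignments(sim$truth, p)
  b <- aln$focal_vs_b[aln$focal_vs_b$query_chrom == "A1", ]
  o <- aln$focal_vs_outgroup[aln$focal_vs_outgroup$query_chrom == "A1", ]
  inv <- call_inversions(chain_synteny(b), query_chrom = "A1")
  truth <- sim$truth$inversions
  expect_equal(nrow(inv), nrow(truth))
  # recovered at block resolution
  expect_true(all(abs(inv$start - truth$start) <= p$block_len))
  expect_true(all(abs(inv$end - truth$end) <= p$block_len))
  inv <- polarize_inversions(inv, o)
  expect_identical(inv$lineage, truth$lineage)
  # strand symmetry: flipping all block strands inverts the call set
  b_flip <- b
  b_flip$strand <- ifelse(b$strand == "+", "-", "+")
  inv_flip <- call_inversions(chain_synteny(b_flip), query_chrom = "A1")
  outside <- rep(TRUE, nrow(inv_flip))
  for (i in seq_len(nrow(truth)))
    outside <- outside & (inv_flip$end <= truth$start[i] + p$block_len |
                            inv_flip$start >= truth$end[i] - p$block_len)
  expect_true(all(outside))
})

test_that("unpolarizable inversions stay unpolarized", {
  inv <- data.frame(chrom = "q", start = 1e5, end = 2e5, length = 1e5,
                    target_start = 1e5, target_end = 2e5, n_blocks = 3L,
                    lineage = "unpolarized", stringsAsFactors = FALSE)
  # no outgroup coverage
  og <- mk_blocks(5e5, 6e5, "+")
  expect_identical(polarize_inversions(inv, og)$lineage, "unpolarized")
  # full "-" coverage -> focal; full "+" -> other
  og2 <- mk_blocks(c(1e5, 1.5e5), c(1.5e5, 2e5), "-")
  expect_identical(polarize_inversions(inv, og2)$lineage, "focal")
  og3 <- mk_blocks(c(1e5, 1.5e5), c(1.5e5, 2e5), "+")
  expect_identical(polarize_inversions(inv, og3)$lineage, "other")
})

test_that("breakpoints sit at inversion ends, padded and clipped", {
  inv <- data.frame(chrom = "q", start = 100000, end = 200000)
  bp <- breakpoints(inv)
  expect_equal(bp$start, c(100000, 200000))
  expect_equal(bp$end - bp$start, c(1, 1))
  bp5 <- breakpoints(inv, pad = 5000)
  expect_equal(bp5$end - bp5$start, c(10001, 10001))
  bp0 <- breakpoints(data.frame(chrom = "q", start = 2000, end = 50000),
                     pad = 5000, chrom_length = 52000)
  expect_equal(bp0$start[1], 0)
  expect_equal(bp0$end[2], 52000)
})

test_that("permutation p floor and reproducibility", {
  bnd <- data.frame(start = 1:10 * 1e5)
  inv <- data.frame(chrom = "q", start = c(1e5, 3e5), end = c(2e5, 4e5))
  bp <- breakpoints(inv)
  r1 <- breakpoint_boundary_overlap(bp, bnd, 2e6, slack = 1e4,
                                    n_perm = 200, seed = 3)
  expect_equal(r1$observed, 4)
  expect_equal(r1$p, 1 / 201)
  r2 <- breakpoint_boundary_overlap(bp, bnd, 2e6, slack = 1e4,
                                    n_perm = 200, seed = 3)
  expect_identical(r1$p, r2$p)
  expect_equal(unname(r1$categories), c(2, 0, 0))
  expect_error(breakpoint_boundary_overlap(bp[0, ], bnd, 2e6),
               "no breakpoints")
  expect_error(breakpoint_boundary_overlap(bp, bnd, 2e6, n_perm = 10),
               ">= 100")
})

test_that("compare_region_values matches rank-sum expectations", {
  tr <- window_track("c", 100, c(rep(0, 20), rep(1, 20)))
  a <- data.frame(start = 0, end = 2000)
  b <- data.frame(start = 2000, end = 4000)
  r <- compare_region_values(tr, a, b)
  expect_lt(r$p, 1e-6)
  expect_equal(r$statistic, 0)  # group A uniformly smaller
  # identical value multisets -> p = 1
  tr2 <- window_track("c", 100, rep(c(1, 2), 20))
  r2 <- compare_region_values(tr2, a, b)
  expect_equal(r2$p, 1)
  expect_error(compare_region_values(tr, a,
                                     data.frame(start = 3900, end = 4000)),
               "at least 2")
})

test_that("insulation at planted boundaries is lower than TAD interiors", {
  p <- sim_params(seed = 29, compartment_strength = 0)
  ends <- c(25L, 60L, 95L, 130L, 160L)
  truth <- hic_truth(160, ends)
  bal <- ice_normalize(simulate_hic(truth, p, "c1"))
  ins <- insulation_score(bal$matrix, 10)
  bs <- 1e4
  bnd_bins <- utils::head(ends, -1)
  regions_a <- data.frame(start = (bnd_bins - 1) * bs,
                          end = (bnd_bins + 1) * bs)
  mids <- utils::head(ends, -1) - 12     # interior bins
  regions_b <- data.frame(start = (mids - 4) * bs, end = mids * bs)
  r <- compare_region_values(ins, regions_a, regions_b)
  expect_lt(r$median_a, r$median_b)
  expect_lt(r$p, 0.05)
})
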