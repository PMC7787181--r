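# Synthetic genomes with planted, recorded truth: sequences, sexed depth
# tracks, Hi-C matrices, alignment blocks and expression matrices.  Every
# planted feature is written into the returned truth record so that the
# analysis modules can be scored against it.

# default centromeric monomer: a fixed 190-bp unit
.default_monomer <- paste0(
  "GTCTACAGGCACCACCAAGTATTCTCGTTTGCCCCACGACGTACTTGCCGGCCGTCCCGT",
  "CTATCGTTTGGGTCCGATGTAGCAGTAAGGGTTAACAACTTTTCAGGAGGAACAGGAGTG",
  "TCTGTAGTCCGAATGGATCATATGGTTACGCCATTTCCTATATACCGGCGACAGCCAGCA",
  "TTGGAAAAGG")

#' Derive a reproducible stage seed from a global seed
#'
#' Stable string hashing so each pipeline stage can be re-run in
#' isolation with the same draws.  Result is always in \[1, 2^31 - 2\].
#'
#' @param seed integer global seed.
#' @param label stage label.
#' @return derived integer seed.
#' @export
derive_seed <- function(seed, label) {
  m <- 2147483647
  h <- Reduce(function(a, b) (a * 31 + b) %% m, utf8ToInt(label), 17)
  as.integer((abs(seed) %% m * 48271 + h) %% (m - 1) + 1)
}

#' Simulation parameters
#'
#' Bundles every tunable of the synthetic-data generators.  Defaults
#' describe the stated toy world: 30x mean depth with negative-binomial
#' dispersion 0.1, Hi-C distance-decay exponent 1 with 3-fold intra-TAD
#' enrichment and compartment strength 0.5, divergence noise sd 0.02,
#' 3-kb palindrome arms, a 190-bp centromeric monomer and the vertebrate
#' telomere motif TTAGGG.
#'
#' @param seed integer; fixes every draw.
#' @param mean_depth mean per-bp read depth of a diploid (2-copy) region.
#' @param depth_dispersion negative-binomial dispersion of per-window
#'   read counts (variance = mu + dispersion * mu^2); 0.01 gives the
#'   ~10 percent window-to-window coefficient of variation typical of
#'   short-read genome coverage.
#' @param read_len read length (bp) used to convert depth to window
#'   read counts.
#' @param hic_decay_exponent contact decay exponent alpha in
#'   (d+1)^(-alpha).
#' @param hic_base expected contact count at distance 0 before TAD /
#'   compartment modulation.
#' @param tad_enrichment multiplicative intra-TAD contact factor.
#' @param compartment_strength extra same-compartment contact fraction.
#' @param divergence_noise_sd sd of window-level divergence noise.
#' @param palindrome_arm_len,spacer_len default planted palindrome arm
#'   and spacer lengths (bp).
#' @param monomer centromeric monomer sequence (190 bp default).
#' @param telomere_motif telomeric repeat unit.
#' @param hic_bin_size Hi-C bin width (bp).
#' @param block_len alignment-block length used by the alignment
#'   simulator (bp).
#' @return list of class `sim_params`.
#' @export
sim_params <- function(seed = 1L, mean_depth = 30,
                       depth_dispersion = 0.01, read_len = 150,
                       hic_decay_exponent = 1, hic_base = 60,
                       tad_enrichment = 3, compartment_strength = 0.5,
                       divergence_noise_sd = 0.02,
                       palindrome_arm_len = 3000, spacer_len = 1000,
                       monomer = .default_monomer,
                       telomere_motif = "TTAGGG",
                       hic_bin_size = 10000, block_len = 5000) {
  p <- list(seed = as.integer(seed), mean_depth = mean_depth,
            depth_dispersion = depth_dispersion, read_len = read_len,
            hic_decay_exponent = hic_decay_exponent, hic_base = hic_base,
            tad_enrichment = tad_enrichment,
            compartment_strength = compartment_strength,
            divergence_noise_sd = divergence_noise_sd,
            palindrome_arm_len = palindrome_arm_len,
            spacer_len = spacer_len, monomer = monomer,
            telomere_motif = telomere_motif, hic_bin_size = hic_bin_size,
            block_len = block_len)
  num <- vapply(p[setdiff(names(p),
                          c("seed", "monomer", "telomere_motif",
                            "compartment_strength"))],
                function(x) is.numeric(x) && x > 0, logical(1))
  if (any(!num) || p$compartment_strength < 0)
    stop("sim_params values must be positive")
  class(p) <- "sim_params"
  p
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute bases at the given per-site rate; identity-only divergence
.mutate_seq <- function(seq, rate) {
  v <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(v)) < rate)
  if (length(hit)) {
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    v[hit] <- vapply(v[hit], function(b) sample(alt[[b]], 1L), "")
  }
  paste(v, collapse = "")
}

.tile_sizes <- function(n_bins, lo, hi) {
  sizes <- integer(0)
  left <- n_bins
  while (left > 0) {
    s <- sample(lo:hi, 1L)
    if (left - s < lo) s <- left
    sizes <- c(sizes, s)
    left <- left - s
  }
  sizes
}

#' Simulate a toy genome with planted truth
#'
#' Generates 4 autosomes (2 macro, 2 micro), a Z with a terminal
#' pseudoautosomal region (PAR), and a W derived from Z segments mutated
#' at 4 planted strata divergence levels, plus centromeric monomer
#' arrays, terminal telomere arrays, an interstitial telomeric repeat
#' (ITR), W palindromes, TAD/compartment bin structure and planted
#' inversions polarizable by an outgroup.  Every planted feature is
#' recorded in the returned truth object.
#'
#' @param params a [sim_params()].
#' @param chrom_lengths named lengths for A1, A2, A3, A4, Z (bp).
#' @param par_len PAR length at the start (tip) of Z.
#' @param strata_divergence divergence level per stratum, oldest first.
#' @param n_w_scaffolds_per_stratum W scaffolds drawn from each stratum.
#' @param w_scaffold_len length of each W scaffold (bp).
#' @param n_palindromes palindromes planted in the W-specific tail.
#' @param inversion_sizes planted inversion sizes on A1 (bp).
#' @param inversion_lineages lineage per inversion, `"focal"` or
#'   `"other"`.
#' @return list with `sequences` (named character vector, W assembled
#'   from its scaffolds) and `truth` (see Details).
#' @details The truth record contains: `chrom_lengths`, `par_interval`,
#'   `strata`, `w_scaffolds`, `scaffolds` (a scaffold decomposition with
#'   true depth-class labels), `tads`, `compartments` (per chromosome,
#'   Hi-C bin units), `inversions`, `centromeres`, `telomeres`, `itrs`,
#'   `palindromes`, `sex_copy` and `hic_bin_size`.
#' @export
simulate_genome <- function(params = sim_params(),
                            chrom_lengths = c(A1 = 2e6, A2 = 2e6,
                                              A3 = 5e5, A4 = 5e5,
                                              Z = 1.5e6),
                            par_len = 1e5,
                            strata_divergence = c(0.24, 0.16, 0.09, 0.03),
                            n_w_scaffolds_per_stratum = 2,
                            w_scaffold_len = 65000,
                            n_palindromes = 3,
                            inversion_sizes = c(2e4, 4e4, 6e4, 1e5,
                                                1.5e5, 2e5),
                            inversion_lineages = c("focal", "other",
                                                   "focal", "focal",
                                                   "other", "focal")) {
  set.seed(derive_seed(params$seed, "genome"))
  if (par_len >= chrom_lengths[["Z"]]) stop("PAR exceeds Z length")
  seqs <- lapply(chrom_lengths, .random_dna)
  names(seqs) <- names(chrom_lengths)

  k <- length(strata_divergence)
  z_len <- chrom_lengths[["Z"]]
  sdr_len <- z_len - par_len
  s_len <- floor(sdr_len / k)
  strata <- data.frame(
    chrom = "Z", name = paste0("S", seq_len(k) - 1L),
    start = par_len + (seq_len(k) - 1L) * s_len,
    end = par_len + seq_len(k) * s_len,
    divergence = strata_divergence, stringsAsFactors = FALSE)
  strata$end[k] <- z_len

  # W scaffolds: copy-and-mutate from non-overlapping Z SDR segments
  wsc <- list()
  for (si in seq_len(k)) {
    span <- strata$end[si] - strata$start[si]
    npick <- n_w_scaffolds_per_stratum
    if (npick * w_scaffold_len > span)
      stop("requested W scaffolds exceed stratum length")
    gap <- floor((span - npick * w_scaffold_len) / (npick + 1))
    for (j in seq_len(npick)) {
      zs <- strata$start[si] + j * gap + (j - 1) * w_scaffold_len
      wsc[[length(wsc) + 1L]] <- data.frame(
        name = sprintf("W_s%d_%d", si - 1L, j), stratum = si - 1L,
        z_start = zs, z_end = zs + w_scaffold_len,
        divergence = strata$divergence[si], stringsAsFactors = FALSE)
    }
  }
  w_scaffolds <- do.call(rbind, wsc)
  w_seqs <- character(nrow(w_scaffolds))
  for (i in seq_len(nrow(w_scaffolds))) {
    src <- substr(seqs[["Z"]], w_scaffolds$z_start[i] + 1,
                  w_scaffolds$z_end[i])
    w_seqs[i] <- .mutate_seq(src, w_scaffolds$divergence[i])
  }
  w_scaffolds$length <- nchar(w_seqs)
  w_scaffolds$w_offset <- cumsum(c(0, utils::head(w_scaffolds$length, -1)))

  # W-specific tail carrying the palindromes
  arm <- params$palindrome_arm_len
  spacers <- params$spacer_len * seq_len(n_palindromes)
  tail_units <- 2 * arm * n_palindromes + sum(spacers) +
    5000 * (n_palindromes + 1)
  w_core_len <- sum(w_scaffolds$length)
  tail_seq <- .random_dna(tail_units)
  pal <- list()
  pos <- 5000
  for (i in seq_len(n_palindromes)) {
    a1 <- .random_dna(arm)
    a2 <- revcomp(a1)
    sp <- spacers[i]
    substr(tail_seq, pos + 1, pos + arm) <- a1
    substr(tail_seq, pos + arm + sp + 1, pos + 2 * arm + sp) <- a2
    pal[[i]] <- data.frame(chrom = "W",
                           arm1_start = w_core_len + pos,
                           arm1_end = w_core_len + pos + arm,
                           arm2_start = w_core_len + pos + arm + sp,
                           arm2_end = w_core_len + pos + 2 * arm + sp,
                           identity = 1, stringsAsFactors = FALSE)
    pos <- pos + 2 * arm + sp + 5000
  }
  palindromes <- do.call(rbind, pal)
  seqs[["W"]] <- paste0(paste(w_seqs, collapse = ""), tail_seq)
  chrom_lengths <- c(chrom_lengths, W = nchar(seqs[["W"]]))

  # centromeric monomer arrays (A1, A2, Z), ~200 copies each
  plant <- function(seq, at, unit, n_copies) {
    arr <- strrep(unit, n_copies)
    substr(seq, at + 1, at + nchar(arr)) <- arr
    list(seq = seq, interval = c(at, at + nchar(arr)))
  }
  cen <- list()
  for (cn in c("A1", "A2", "Z")) {
    at <- round(chrom_lengths[[cn]] * 0.45)
    pl <- plant(seqs[[cn]], at, params$monomer, 200L)
    seqs[[cn]] <- pl$seq
    cen[[cn]] <- data.frame(chrom = cn, start = pl$interval[1],
                            end = pl$interval[2], copies = 200L,
                            stringsAsFactors = FALSE)
  }
  centromeres <- do.call(rbind, cen)
  rownames(centromeres) <- NULL

  # terminal telomere arrays on every chromosome end except W; one ITR
  tel <- list()
  tel_copies <- 400L
  tel_len <- tel_copies * nchar(params$telomere_motif)
  for (cn in c("A1", "A2", "A3", "A4", "Z")) {
    L <- chrom_lengths[[cn]]
    pl <- plant(seqs[[cn]], 0, params$telomere_motif, tel_copies)
    seqs[[cn]] <- pl$seq
    pl2 <- plant(seqs[[cn]], L - tel_len, params$telomere_motif,
                 tel_copies)
    seqs[[cn]] <- pl2$seq
    tel[[cn]] <- data.frame(chrom = cn,
                            start = c(0, L - tel_len),
                            end = c(tel_len, L),
                            copies = tel_copies, stringsAsFactors = FALSE)
  }
  telomeres <- do.call(rbind, tel)
  rownames(telomeres) <- NULL
  itr_at <- round(chrom_lengths[["A2"]] * 0.7)
  pl <- plant(seqs[["A2"]], itr_at, params$telomere_motif, tel_copies)
  seqs[["A2"]] <- pl$seq
  itrs <- data.frame(chrom = "A2", start = pl$interval[1],
                     end = pl$interval[2], copies = tel_copies,
                     stringsAsFactors = FALSE)

  # TAD and compartment truth per chromosome, in Hi-C bin units
  bs <- params$hic_bin_size
  tads <- list(); compartments <- list()
  for (cn in c("A1", "A2", "A3", "A4", "Z")) {
    nb <- ceiling(chrom_lengths[[cn]] / bs)
    sizes <- .tile_sizes(nb, 20L, 60L)
    ends <- cumsum(sizes)
    tads[[cn]] <- data.frame(start_bin = c(0L, utils::head(ends, -1)),
                             end_bin = ends)
    # compartment blocks are unions of 1-2 consecutive TADs, so every
    # compartment transition coincides with a TAD boundary (as in real
    # chromatin)
    n_tads <- length(sizes)
    per_block <- sample(1:2, n_tads, replace = TRUE)
    per_block <- per_block[cumsum(per_block) <= n_tads]
    if (sum(per_block) < n_tads)
      per_block <- c(per_block, n_tads - sum(per_block))
    block_of_tad <- rep(seq_along(per_block), per_block)
    lab_block <- rep(c("A", "B"), length.out = length(per_block))
    compartments[[cn]] <- rep(lab_block[block_of_tad], sizes)
  }

  # planted inversions on A1, non-overlapping, with lineage labels
  stopifnot(length(inversion_sizes) == length(inversion_lineages))
  n_inv <- length(inversion_sizes)
  inv <- NULL
  if (n_inv > 0) {
    L <- chrom_lengths[["A1"]]
    gap <- floor((L - sum(inversion_sizes)) / (n_inv + 1))
    if (gap < 2 * params$block_len)
      stop("inversions exceed chromosome length")
    st <- gap + cumsum(c(0, utils::head(inversion_sizes, -1) +
                           rep(gap, n_inv - 1)))
    inv <- data.frame(chrom = "A1", start = st,
                      end = st + inversion_sizes,
                      lineage = inversion_lineages,
                      stringsAsFactors = FALSE)
  }

  sex_copy <- data.frame(
    name = c("A1", "A2", "A3", "A4", "Z", "W"),
    male = c(2, 2, 2, 2, 2, 0), female = c(2, 2, 2, 2, 1, 1),
    stringsAsFactors = FALSE)

  # scaffold decomposition with true depth-class labels (PAR scaffolds
  # look autosomal by depth; no scaffold spans the PAR boundary)
  scf <- list()
  cut_chrom <- function(cn, lo, hi, label, region) {
    if (hi - lo < 50000) return(NULL)
    n_parts <- max(1L, floor((hi - lo) / 1e5))
    bounds <- round(seq(lo, hi, length.out = n_parts + 1))
    data.frame(name = sprintf("%s_p%02d", cn, seq_len(n_parts)),
               chrom = cn, start = utils::head(bounds, -1),
               end = bounds[-1], label = label, region = region,
               stringsAsFactors = FALSE)
  }
  for (cn in c("A1", "A2", "A3", "A4"))
    scf[[cn]] <- cut_chrom(cn, 0, chrom_lengths[[cn]], "autosomal", "auto")
  scf[["Zpar"]] <- cut_chrom("Z", 0, par_len, "autosomal", "PAR")
  scf[["Zsdr"]] <- cut_chrom("Z", par_len, z_len, "Z", "SDR")
  scf[["W"]] <- cut_chrom("W", 0, chrom_lengths[["W"]], "W", "W")
  scaffolds <- do.call(rbind, scf)
  rownames(scaffolds) <- NULL

  truth <- list(chrom_lengths = chrom_lengths,
                par_interval = data.frame(chrom = "Z", start = 0,
                                          end = par_len),
                strata = strata, w_scaffolds = w_scaffolds,
                scaffolds = scaffolds, tads = tads,
                compartments = compartments, inversions = inv,
                centromeres = centromeres, telomeres = telomeres,
                itrs = itrs, palindromes = palindromes,
                sex_copy = sex_copy, hic_bin_size = bs)
  list(sequences = unlist(seqs), truth = truth)
}

.copies_for <- function(truth, name, sex) {
  sc <- truth$sex_copy
  row <- sc[sc$name == name, ]
  if (nrow(row) == 0) stop("unknown chromosome: ", name)
  if (sex == "M") row$male else row$female
}

#' Simulate a sexed per-window depth track
#'
#' Per-window read counts are drawn negative-binomially with mean
#' `mean_depth * copies / 2 * window_size / read_len` and converted
#' back to per-bp depth, so a window's value aggregates many reads as
#' in real coverage tracks; Z windows inside the PAR use 2 copies in
#' both sexes.
#'
#' @param truth a `simulate_genome()` truth record.
#' @param params a [sim_params()].
#' @param sex `"M"` or `"F"`.
#' @param chrom chromosome name present in `truth$sex_copy`.
#' @param window_size window width (bp).
#' @param start,end optional sub-interval of the chromosome (a scaffold);
#'   defaults to the whole chromosome.
#' @return a [window_track()] of simulated depths.
#' @export
simulate_depth <- function(truth, params, sex = c("M", "F"), chrom,
                           window_size = 5000, start = 0, end = NULL) {
  sex <- match.arg(sex)
  set.seed(derive_seed(params$seed,
                       paste("depth", chrom, sex, start, sep = "_")))
  copies <- .copies_for(truth, chrom, sex)
  if (is.null(end)) end <- truth$chrom_lengths[[chrom]]
  starts <- seq(start, end - 1, by = window_size)
  cop <- rep(copies, length(starts))
  if (chrom == "Z") {
    par_end <- truth$par_interval$end
    cop[starts + window_size / 2 < par_end] <- 2
  }
  per_read <- params$read_len / window_size
  mu_reads <- params$mean_depth * cop / 2 / per_read
  counts <- stats::rnbinom(length(starts),
                           size = 1 / params$depth_dispersion,
                           mu = mu_reads)
  window_track(chrom, window_size, counts * per_read,
               chrom_length = end - start)
}

#' Simulate a Hi-C contact matrix with planted TADs and compartments
#'
#' Expected counts follow a power-law distance decay multiplied by
#' `tad_enrichment` for intra-TAD bin pairs and `1 +
#' compartment_strength` for same-compartment pairs; counts are Poisson
#' sampled and symmetric.
#'
#' @param truth truth record carrying `tads` and `compartments` for
#'   `chrom`.
#' @param params a [sim_params()].
#' @param chrom chromosome to simulate.
#' @return a [contact_matrix()].
#' @export
simulate_hic <- function(truth, params, chrom) {
  if (is.null(truth$tads[[chrom]])) stop("no TAD truth for ", chrom)
  set.seed(derive_seed(params$seed, paste0("hic_", chrom)))
  nb <- ceiling(truth$chrom_lengths[[chrom]] / params$hic_bin_size)
  td <- truth$tads[[chrom]]
  tad_of <- integer(nb)
  for (i in seq_len(nrow(td)))
    tad_of[(td$start_bin[i] + 1):td$end_bin[i]] <- i
  comp <- truth$compartments[[chrom]]
  d <- abs(outer(seq_len(nb), seq_len(nb), "-"))
  mu <- params$hic_base * (d + 1)^(-params$hic_decay_exponent)
  same_tad <- outer(tad_of, tad_of, "==")
  mu <- mu * ifelse(same_tad, params$tad_enrichment, 1)
  same_comp <- outer(comp, comp, "==")
  mu <- mu * (1 + params$compartment_strength * same_comp)
  up <- upper.tri(mu, diag = TRUE)
  counts <- matrix(0, nb, nb)
  counts[up] <- stats::rpois(sum(up), mu[up])
  counts <- counts + t(counts) - diag(diag(counts))
  contact_matrix(chrom, params$hic_bin_size, counts)
}

.tile_blocks <- function(len, block_len) {
  starts <- seq(0, len - 1, by = block_len)
  ends <- pmin(starts + block_len, len)
  keep <- ends - starts >= block_len / 2
  cbind(starts[keep], ends[keep])
}

# map focal blocks through the inversion set of one comparison:
# blocks fully inside an inverted interval flip strand and mirror their
# target coordinates within the interval
.apply_inversions <- function(blk, inv) {
  if (is.null(inv) || nrow(inv) == 0) return(blk)
  for (i in seq_len(nrow(inv))) {
    s <- inv$start[i]; e <- inv$end[i]
    hit <- blk$query_chrom == inv$chrom[i] & blk$query_start >= s &
      blk$query_end <= e
    blk$strand[hit] <- "-"
    ts <- s + e - blk$query_end[hit]
    te <- s + e - blk$query_start[hit]
    blk$target_start[hit] <- ts
    blk$target_end[hit] <- te
  }
  blk
}

#' Simulate pairwise alignment blocks
#'
#' Produces three block sets: focal-vs-speciesB and focal-vs-outgroup
#' (collinear except at planted inversions; focal-lineage inversions
#' flip strand in both comparisons, B-lineage inversions only in
#' focal-vs-B), and W-scaffold-vs-outgroup-Z blocks whose
#' matches/aln_len reflect each stratum's planted divergence.
#'
#' @param truth truth record with `inversions` and `w_scaffolds`.
#' @param params a [sim_params()].
#' @param base_identity identity of collinear autosomal blocks.
#' @return list with `focal_vs_b`, `focal_vs_outgroup`, `w_vs_z`, each an
#'   [alignment_blocks()] data.frame.
#' @export
simulate_alignments <- function(truth, params, base_identity = 0.98) {
  set.seed(derive_seed(params$seed, "alignments"))
  bl <- params$block_len
  mk <- function(chroms) {
    out <- lapply(chroms, function(cn) {
      t <- .tile_blocks(truth$chrom_lengths[[cn]], bl)
      len <- t[, 2] - t[, 1]
      alignment_blocks(cn, t[, 1], t[, 2], cn, t[, 1], t[, 2], "+",
                       stats::rbinom(nrow(t), len, base_identity), len)
    })
    do.call(rbind, out)
  }
  chroms <- setdiff(names(truth$chrom_lengths), "W")
  base <- mk(chroms)
  inv <- truth$inversions
  fvb <- .apply_inversions(base, inv)
  fvo <- .apply_inversions(mk(chroms),
                           inv[inv$lineage == "focal", , drop = FALSE])
  fvb$target_chrom <- paste0("B_", fvb$target_chrom)
  fvo$target_chrom <- paste0("O_", fvo$target_chrom)

  wvz <- lapply(seq_len(nrow(truth$w_scaffolds)), function(i) {
    w <- truth$w_scaffolds[i, ]
    t <- .tile_blocks(w$length, bl)
    len <- t[, 2] - t[, 1]
    alignment_blocks(w$name, t[, 1], t[, 2], "Z",
                     w$z_start + t[, 1], w$z_start + t[, 2], "+",
                     stats::rbinom(nrow(t), len, 1 - w$divergence), len)
  })
  list(focal_vs_b = fvb, focal_vs_outgroup = fvo,
       w_vs_z = do.call(rbind, wvz))
}

#' Simulate a tissue-by-sex expression matrix
#'
#' Log-normal expression with planted structure: Z-SDR genes have a
#' male mean twice the female mean; housekeeping genes are near-uniform
#' across tissues; tissue-specific genes are expressed in one tissue.
#'
#' @param truth truth record (used for chromosome labels).
#' @param params a [sim_params()].
#' @param n_tissues number of tissues, >= 2.
#' @param n_per_sex replicates per sex per tissue.
#' @param n_auto,n_z autosomal and Z-SDR gene counts.
#' @param n_housekeeping,n_tissue_specific planted expression classes
#'   (taken from the autosomal pool).
#' @return list with `expr` (genes x samples matrix), `genes`
#'   (metadata: chrom, class) and `samples` (tissue, sex).
#' @export
simulate_expression <- function(truth, params, n_tissues = 5,
                                n_per_sex = 3, n_auto = 300, n_z = 200,
                                n_housekeeping = 20,
                                n_tissue_specific = 20) {
  if (n_tissues < 2) stop("need at least 2 tissues")
  set.seed(derive_seed(params$seed, "expression"))
  n_genes <- n_auto + n_z
  genes <- data.frame(
    gene = sprintf("g%04d", seq_len(n_genes)),
    chrom = c(rep("A1", n_auto), rep("Z", n_z)),
    class = "regular", stringsAsFactors = FALSE)
  genes$class[seq_len(n_housekeeping)] <- "housekeeping"
  genes$class[n_housekeeping + seq_len(n_tissue_specific)] <-
    "tissue_specific"
  spec_tissue <- sample(n_tissues, n_tissue_specific, replace = TRUE)

  samples <- expand.grid(rep = seq_len(n_per_sex), sex = c("M", "F"),
                         tissue = paste0("t", seq_len(n_tissues)),
                         stringsAsFactors = FALSE)
  base_mu <- stats::rnorm(n_genes, 3, 1)
  expr <- matrix(0, n_genes, nrow(samples),
                 dimnames = list(genes$gene, sprintf(
                   "%s_%s_r%d", samples$tissue, samples$sex, samples$rep)))
  tissue_effect <- matrix(stats::rnorm(n_genes * n_tissues, 0, 0.5),
                          n_genes, n_tissues)
  tissue_effect[genes$class == "housekeeping", ] <- 0
  ts_rows <- which(genes$class == "tissue_specific")
  for (j in seq_len(nrow(samples))) {
    ti <- as.integer(sub("t", "", samples$tissue[j]))
    mu <- base_mu + tissue_effect[, ti]
    mu[ts_rows] <- ifelse(spec_tissue == ti, base_mu[ts_rows] + 1, -6)
    if (samples$sex[j] == "M") mu[genes$chrom == "Z"] <-
        mu[genes$chrom == "Z"] + log(2)
    expr[, j] <- exp(stats::rnorm(n_genes, mu, 0.2))
  }
  list(expr = expr, genes = genes, samples = samples)
}
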