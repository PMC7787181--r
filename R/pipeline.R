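# Orchestrate the synthetic-to-report workflow (and a file-driven
# workflow) from one config: simulate -> sexlink -> strata -> hic ->
# rearrange -> repeats, with a machine-readable results bundle.

#' Read a bedGraph file into a window track
#'
#' @param path bedGraph path (chrom, start, end, value).
#' @param chrom_length chromosome length (bp).
#' @param window_size window width the intervals are assumed to tile.
#' @return a [window_track()]; windows absent from the file are
#'   missing.
#' @export
read_bedgraph_track <- function(path, chrom_length, window_size) {
  tab <- utils::read.table(path,
                           col.names = c("chrom", "start", "end",
                                         "value"))
  n <- ceiling(chrom_length / window_size)
  vals <- rep(NA_real_, n)
  vals[floor(tab$start / window_size) + 1] <- tab$value
  window_track(tab$chrom[1], window_size, vals,
               chrom_length = chrom_length)
}

#' Validate a pipeline run configuration
#'
#' @param config list (or path to a JSON file) with fields: exactly one
#'   of `simulate` (a list of [sim_params()] overrides) or `inputs`
#'   (named file paths), plus optional `seed`, `out_dir`, and per-stage
#'   parameter overrides (`sexlink`, `strata`, `hic`, `rearrange`,
#'   `repeats`).
#' @return normalized config list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  has_sim <- !is.null(config$simulate)
  has_inp <- !is.null(config$inputs)
  if (has_sim == has_inp)
    stop("config must contain exactly one of 'simulate' or 'inputs'")
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$out_dir)) config$out_dir <- tempfile("chromarch_")
  config
}

.log_stage <- function(verbose, ...) {
  if (verbose) message(sprintf(...))
}

#' Run the full pipeline
#'
#' In simulate mode every analysis stage runs on freshly generated
#' synthetic data and the bundle includes a truth-recovery table; in
#' inputs mode each stage runs if (and only if) its input files are
#' present.  A single global seed is propagated to every stochastic
#' stage through [derive_seed()].
#'
#' @param config see [validate_config()].
#' @param verbose emit progress messages to stderr.
#' @return list of class `results_bundle`: `manifest` (stage -> files),
#'   `summary` (metrics per stage), `recovery` (truth-recovery table,
#'   simulate mode only), `out_dir`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  config <- validate_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(); summary <- list(); recovery <- list()
  add <- function(stage, files) manifest[[stage]] <<-
    c(manifest[[stage]], files)

  if (!is.null(config$simulate)) {
    pargs <- config$simulate
    pargs$seed <- config$seed
    params <- do.call(sim_params, pargs)
    .log_stage(verbose, "simulate: generating genome")
    sim <- simulate_genome(params)
    truth <- sim$truth
    fa <- file.path(out, "genome.fa")
    write_fasta(sim$sequences, fa)
    tj <- file.path(out, "truth.json")
    jsonlite::write_json(truth[setdiff(names(truth),
                                       c("tads", "compartments"))],
                         tj, auto_unbox = TRUE, digits = NA)
    add("simulate", c(fa, tj))

    # --- sexlink -------------------------------------------------
    .log_stage(verbose, "sexlink: classifying scaffolds")
    scf <- truth$scaffolds
    med <- params$mean_depth
    mk_tracks <- function(sex) {
      tr <- lapply(seq_len(nrow(scf)), function(i)
        normalize_depth(simulate_depth(truth, params, sex,
                                       chrom = scf$chrom[i],
                                       start = scf$start[i],
                                       end = scf$end[i]), med))
      for (i in seq_along(tr)) tr[[i]]$chrom <- scf$name[i]
      stats::setNames(tr, scf$name)
    }
    trM <- mk_tracks("M"); trF <- mk_tracks("F")
    calls <- classify_scaffolds(trM, trF)
    sex_tsv <- file.path(out, "sex_calls.tsv")
    utils::write.table(calls, sex_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add("sexlink", sex_tsv)
    acc <- mean(calls$label == scf$label)
    summary$sexlink <- list(n_scaffolds = nrow(calls),
                            label_accuracy = acc)
    recovery$sexlink_label_accuracy <- acc

    mz <- simulate_depth(truth, params, "M", "Z")
    fz <- simulate_depth(truth, params, "F", "Z")
    ratio <- window_track("Z", mz$window_size,
                          (mz$values + 0.5) / (fz$values + 0.5),
                          chrom_length = mz$chrom_length)
    par_call <- detect_par(ratio)
    if (!is.null(par_call)) {
      par_bed <- file.path(out, "par.bed")
      write_bed(par_call$par_interval, par_bed)
      add("sexlink", par_bed)
      err <- abs(par_call$boundary - truth$par_interval$end)
      summary$par <- list(boundary = par_call$boundary,
                          error_bp = err)
      recovery$par_boundary_error_windows <- err / mz$window_size
    }

    # --- strata --------------------------------------------------
    .log_stage(verbose, "strata: W/Z divergence segmentation")
    aln <- simulate_alignments(truth, params)
    wd <- windowed_divergence(aln$w_vs_z, truth$chrom_lengths[["Z"]])
    seg <- segment_strata(wd$track, k = "auto",
                          scaffold_of = wd$scaffold_of)
    strata_bed <- file.path(out, "strata.bed")
    sb <- seg$strata; sb$chrom <- "Z"; sb$name <- sb$name
    write_bed(sb[, c("chrom", "start", "end", "name")], strata_bed)
    add("strata", strata_bed)
    summary$strata <- list(k = seg$k,
                           means = seg$strata$mean_divergence)
    recovery$strata_k <- seg$k

    # --- hic -----------------------------------------------------
    .log_stage(verbose, "hic: TADs and compartments on A1")
    cm <- simulate_hic(truth, params, "A1")
    bal <- ice_normalize(cm)
    ins <- insulation_score(bal$matrix, window_bins = 10)
    bnd <- call_tad_boundaries(ins)
    ins_bg <- file.path(out, "insulation_A1.bedGraph")
    write_bedgraph(ins, ins_bg)
    bnd_bed <- file.path(out, "tad_boundaries_A1.bed")
    write_bed(data.frame(chrom = "A1", start = bnd$start,
                         end = bnd$end,
                         name = sprintf("b%d", seq_len(nrow(bnd))),
                         score = round(bnd$strength, 3)), bnd_bed)
    add("hic", c(ins_bg, bnd_bed))
    true_b <- utils::head(truth$tads[["A1"]]$end_bin, -1)
    f1 <- boundary_f1(bnd$bin, true_b, tol = 1)
    gc <- gc_track(read_fasta(fa)[["A1"]], cm$bin_size, chrom = "A1")
    comp <- ab_compartments(bal$matrix, gc)
    keep <- !is.na(comp$label)
    comp_acc <- max(mean(comp$label[keep] ==
                           truth$compartments[["A1"]][keep]),
                    mean(comp$label[keep] !=
                           truth$compartments[["A1"]][keep]))
    summary$hic <- list(n_boundaries = nrow(bnd), boundary_f1 = f1,
                        compartment_accuracy = comp_acc)
    recovery$tad_boundary_f1 <- f1
    recovery$compartment_accuracy <- comp_acc

    # --- rearrange -----------------------------------------------
    .log_stage(verbose, "rearrange: inversions and breakpoints")
    a1_b <- aln$focal_vs_b[aln$focal_vs_b$query_chrom == "A1", ]
    a1_o <- aln$focal_vs_outgroup[
      aln$focal_vs_outgroup$query_chrom == "A1", ]
    chains <- chain_synteny(a1_b)
    inv <- call_inversions(chains, query_chrom = "A1")
    inv <- polarize_inversions(inv, a1_o)
    inv_bed <- file.path(out, "inversions_A1.bed")
    write_bed(data.frame(chrom = inv$chrom, start = inv$start,
                         end = inv$end, name = inv$lineage), inv_bed)
    add("rearrange", inv_bed)
    n_true <- if (is.null(truth$inversions)) 0 else
      sum(truth$inversions$chrom == "A1")
    summary$rearrange <- list(n_called = nrow(inv), n_true = n_true)
    recovery$inversions_called <- nrow(inv)
    recovery$inversions_true <- n_true
    if (nrow(inv) > 0 && nrow(bnd) > 0) {
      bp <- breakpoints(inv,
                        chrom_length = truth$chrom_lengths[["A1"]])
      enr <- breakpoint_boundary_overlap(
        bp, bnd, truth$chrom_lengths[["A1"]], slack = cm$bin_size,
        n_perm = 200, seed = derive_seed(config$seed, "bp_perm"))
      enr_json <- file.path(out, "breakpoint_enrichment.json")
      jsonlite::write_json(enr, enr_json, auto_unbox = TRUE,
                           digits = NA)
      add("rearrange", enr_json)
      summary$rearrange$enrichment_p <- enr$p
      summary$rearrange$categories <- as.list(enr$categories)
    }

    # --- repeats -------------------------------------------------
    .log_stage(verbose, "repeats: arrays and palindromes")
    seqs <- read_fasta(fa)
    ann <- list()
    for (cn in c("A1", "A2", "Z")) {
      cen_tr <- count_motif_windows(
        seqs[[cn]], params$monomer,
        max_mismatch = round(0.1 * nchar(params$monomer)), chrom = cn)
      ann[[paste0(cn, "_cen")]] <- call_centromeres(cen_tr)
    }
    for (cn in c("A1", "A2", "A3", "A4", "Z")) {
      tel_tr <- count_motif_windows(seqs[[cn]], params$telomere_motif,
                                    chrom = cn)
      ann[[paste0(cn, "_tel")]] <- call_telomeres(tel_tr)
    }
    ann_df <- do.call(rbind, lapply(ann, function(a)
      a[, c("chrom", "start", "end", "kind", "copies")]))
    ann_bed <- file.path(out, "repeat_annotations.bed")
    write_bed(data.frame(chrom = ann_df$chrom, start = ann_df$start,
                         end = ann_df$end, name = ann_df$kind,
                         score = ann_df$copies), ann_bed)
    pal <- find_palindromes(seqs[["W"]], chrom = "W")
    pal_tsv <- file.path(out, "palindromes_W.tsv")
    utils::write.table(pal, pal_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add("repeats", c(ann_bed, pal_tsv))
    summary$repeats <- list(
      n_centromeres = sum(ann_df$kind == "centromere" &
                            !is.na(ann_df$kind)),
      n_telomeres = sum(ann_df$kind == "telomere_terminal"),
      n_itrs = sum(ann_df$kind == "ITR"),
      n_palindromes = nrow(pal))
    recovery$palindromes_called <- nrow(pal)
    recovery$palindromes_true <- nrow(truth$palindromes)
    recovery$itr_called <- sum(ann_df$kind == "ITR")
  } else {
    inp <- config$inputs
    if (!is.null(inp$fasta)) {
      seqs <- read_fasta(inp$fasta)
      pal <- do.call(rbind, lapply(names(seqs), function(cn)
        find_palindromes(seqs[[cn]], chrom = cn)))
      pal_tsv <- file.path(out, "palindromes.tsv")
      utils::write.table(pal, pal_tsv, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      add("repeats", pal_tsv)
      summary$repeats <- list(n_palindromes = nrow(pal))
    }
    if (!is.null(inp$w_vs_z_paf) && !is.null(inp$z_length)) {
      blocks <- read_alignment_blocks(inp$w_vs_z_paf, "paf")
      wd <- windowed_divergence(blocks, inp$z_length)
      seg <- segment_strata(wd$track, k = "auto",
                            scaffold_of = wd$scaffold_of)
      strata_bed <- file.path(out, "strata.bed")
      sb <- seg$strata
      write_bed(data.frame(chrom = "Z", start = sb$start,
                           end = sb$end, name = sb$name), strata_bed)
      add("strata", strata_bed)
      summary$strata <- list(k = seg$k)
    }
    if (!is.null(inp$contacts_coo) && !is.null(inp$n_bins)) {
      cm <- read_contacts_coo(inp$contacts_coo, inp$n_bins,
                              bin_size = inp$bin_size %||% 10000)
      bal <- ice_normalize(cm)
      ins <- insulation_score(bal$matrix)
      bnd <- call_tad_boundaries(ins)
      bnd_bed <- file.path(out, "tad_boundaries.bed")
      write_bed(data.frame(chrom = cm$chrom, start = bnd$start,
                           end = bnd$end), bnd_bed)
      add("hic", bnd_bed)
      summary$hic <- list(n_boundaries = nrow(bnd))
    }
  }

  sj <- file.path(out, "summary.json")
  jsonlite::write_json(list(summary = summary, recovery = recovery,
                            seed = config$seed),
                       sj, auto_unbox = TRUE, digits = NA)
  manifest$summary <- sj
  structure(list(manifest = manifest, summary = summary,
                 recovery = recovery, out_dir = out),
            class = "results_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' F1 score of called vs true boundary bins
#'
#' @param called,truth 0-based boundary bin indices.
#' @param tol matching tolerance in bins.
#' @return F1 in \[0, 1\].
#' @export
boundary_f1 <- function(called, truth, tol = 1) {
  if (!length(called) && !length(truth)) return(1)
  if (!length(called) || !length(truth)) return(0)
  tp_c <- sum(vapply(called, function(b) any(abs(truth - b) <= tol),
                     logical(1)))
  tp_t <- sum(vapply(truth, function(b) any(abs(called - b) <= tol),
                     logical(1)))
  prec <- tp_c / length(called)
  rec <- tp_t / length(truth)
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}
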