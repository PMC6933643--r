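# Benchmark protocols: fixed simulation layouts used to characterise the
# method, exposed as functions so tests and reproduction scripts share one
# definition. The problem sizes are desk-scale replicas of the published
# protocols (see the methods vignette for the reasoning behind each value).

#' Complicated-event reconstruction benchmark
#'
#' Simulates the complicated HGT structure layout — one receptor carrying
#' two HGT events of five 10 kb transferred segments each, in a small
#' microbiome (5 genomes of ~200 kb) — generates error-free paired-end
#' reads from the true local strains at the given depth, runs detection and
#' reconstruction, and scores Reconstruction Accuracy, Detection Rate and
#' breakpoint sensitivity/FDR against the planted truth (20 bp tolerance).
#'
#' @param depth fold coverage (default 30).
#' @param seed RNG seed.
#' @param error_rate per-base substitution rate (default 0: the error-free
#'   setting of the benchmark).
#' @return list: ra, detection_rate, sensitivity, fdr, n_segments,
#'   seq_identical (reconstructed vs true strain sequence).
#' @export
benchmark_strain_reconstruction <- function(depth = 30, seed = 1L,
                                            error_rate = 0) {
  cfg <- sim_config(n_species = 5L, genome_length_range = c(180000L, 220000L),
                    n_events = 2L, segments_per_event = 5L,
                    segment_length = 10000L, depth = depth,
                    read_length = 100L, insert_mean = 500, insert_sd = 50,
                    error_rate = error_rate, seed = seed,
                    single_receptor = TRUE, include_background = FALSE)
  genomes <- generate_reference_set(cfg)
  planted <- plant_hgt_events(genomes, cfg)
  readset <- simulate_reads(planted$strain_seqs, cfg, with_seq = FALSE)
  records <- emit_truth_alignments(readset, planted$truth_segments, genomes,
                                   as_table = TRUE)
  res <- run_hgt_pipeline(records, genomes)
  ev <- evaluate_reconstruction(planted$truth_segments,
                                planted$truth_breakpoints,
                                res$structure, res$breakpoints)
  seq_ok <- FALSE
  if (length(res$sequences)) {
    truth_seq <- as.character(planted$strain_seqs[[1]])
    seq_ok <- any(vapply(seq_along(res$sequences), function(i)
      as.character(res$sequences[[i]]) == truth_seq, logical(1)))
  }
  list(ra = unname(ev$ra[1]), detection_rate = ev$detection_rate,
       sensitivity = ev$sensitivity, fdr = ev$fdr,
       n_segments = nrow(planted$truth_segments[planted$truth_segments$role == "donor"]),
       seq_identical = seq_ok)
}

#' Coverage-series breakpoint-detection benchmark
#'
#' Simulates 20 synthetic genomes (~200 kb), plants 50 single-segment HGT
#' events (100 junction breakpoint pairs), generates paired-end reads from
#' the true local strains with the WGSIM-default geometry the published
#' coverage series used (70 bp reads, 500 +- 50 bp insert, 2% base error)
#' at the requested depth, runs breakpoint detection and scores
#' sensitivity and FDR at 20 bp tolerance.
#'
#' @param depth fold coverage.
#' @param seed RNG seed.
#' @return list: sensitivity, fdr, n_truth, n_calls.
#' @export
benchmark_breakpoint_sensitivity <- function(depth, seed = 1L) {
  cfg <- sim_config(n_species = 20L, genome_length_range = c(180000L, 220000L),
                    n_events = 50L, segments_per_event = 1L,
                    segment_length = 10000L, depth = depth,
                    read_length = 70L, insert_mean = 500, insert_sd = 50,
                    error_rate = 0.02, seed = seed, include_background = FALSE)
  genomes <- generate_reference_set(cfg)
  planted <- plant_hgt_events(genomes, cfg)
  readset <- simulate_reads(planted$strain_seqs, cfg, with_seq = FALSE)
  records <- emit_truth_alignments(readset, planted$truth_segments, genomes,
                                   as_table = TRUE)
  rm(readset); gc(verbose = FALSE)
  bps <- detect_breakpoints(records)
  rm(records); gc(verbose = FALSE)
  sf <- breakpoint_sensitivity_fdr(planted$truth_breakpoints,
                                   bps[bps$precise == TRUE], tol = 20L)
  list(sensitivity = sf$sensitivity, fdr = sf$fdr, n_truth = sf$n_truth,
       n_calls = sf$n_calls)
}
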