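#' Match reconstructed segments to true strain segments
#'
#' A reconstructed segment matches a truth segment when both of its boundary
#' breakpoint positions lie within `tol` bp of the truth segment's
#' boundaries, on the same source reference and orientation. Matching is
#' 1-to-1, greedy by boundary distance (each truth segment used once).
#' The result is a pair of token sequences suitable for the token-level
#' Smith–Waterman: matched reconstructed segments share the truth segment's
#' identity, unmatched ones get unique non-matching identities.
#'
#' @param truth truth segment table for one strain (columns source_ref,
#'   start, end, orientation, ordered by rank).
#' @param recon reconstructed structure table for one strain (same
#'   columns).
#' @param tol boundary tolerance in bp (default 20).
#' @return list with `tokens_truth`, `tokens_recon` (integer vectors;
#'   negative = unmatched) and `n_matched`.
#' @export
match_segments <- function(truth, recon, tol = 20L) {
  truth <- as.data.table(truth); recon <- as.data.table(recon)
  mt <- nrow(truth)
  tokens_truth <- seq_len(mt)
  if (!nrow(recon))
    return(list(tokens_truth = tokens_truth, tokens_recon = integer(0),
                n_matched = 0L))
  cand <- list()
  for (i in seq_len(nrow(recon))) for (j in seq_len(mt)) {
    if (recon$source_ref[i] != truth$source_ref[j]) next
    if (recon$orientation[i] != truth$orientation[j]) next
    d <- max(abs(recon$start[i] - truth$start[j]), abs(recon$end[i] - truth$end[j]))
    if (d <= tol) cand[[length(cand) + 1L]] <- c(i, j, d)
  }
  assign_recon <- rep(NA_integer_, nrow(recon))
  if (length(cand)) {
    cd <- do.call(rbind, cand)
    cd <- cd[order(cd[, 3], cd[, 1], cd[, 2]), , drop = FALSE]
    used_t <- logical(mt); used_r <- logical(nrow(recon))
    for (k in seq_len(nrow(cd))) {
      i <- cd[k, 1]; j <- cd[k, 2]
      if (used_r[i] || used_t[j]) next
      assign_recon[i] <- j; used_r[i] <- TRUE; used_t[j] <- TRUE
    }
  }
  tokens_recon <- ifelse(is.na(assign_recon), -seq_along(assign_recon), assign_recon)
  list(tokens_truth = tokens_truth, tokens_recon = as.integer(tokens_recon),
       n_matched = sum(!is.na(assign_recon)))
}

#' Token-level Smith–Waterman similarity
#'
#' Standard local-alignment dynamic program over segment tokens with
#' `match = 1`, `mismatch = -1` and gap penalty 0 (a deleted segment costs
#' only its missed match).
#'
#' @param a,b token vectors (any atomic type; equality defines a match).
#' @param match,mismatch,gap alignment scores.
#' @return the maximal local alignment score (0 for empty inputs).
#' @export
sw_score <- function(a, b, match = 1, mismatch = -1, gap = 0) {
  la <- length(a); lb <- length(b)
  if (la == 0L || lb == 0L) return(0)
  H <- matrix(0, la + 1L, lb + 1L)
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      s <- if (a[i] == b[j]) match else mismatch
      H[i + 1L, j + 1L] <- max(0, H[i, j] + s, H[i, j + 1L] + gap,
                               H[i + 1L, j] + gap)
    }
  }
  max(H)
}

#' Reconstruction Accuracy of one strain
#'
#' `RA = SW(h, H) / (m * match_score)` where `H` is the true strain of `m`
#' segments and `h` the reconstruction; an empty reconstruction scores 0,
#' and `RA = 1` exactly when every truth segment is matched in order.
#'
#' @param truth,recon segment tables as in [match_segments()]; `recon` may
#'   be `NULL`/empty.
#' @param tol boundary tolerance (bp).
#' @param match_score Smith–Waterman match score.
#' @return RA in [0, 1].
#' @export
reconstruction_accuracy <- function(truth, recon, tol = 20L, match_score = 1) {
  truth <- as.data.table(truth)
  m <- nrow(truth)
  if (m < 1L) stopf("truth strain must have at least one segment")
  if (is.null(recon) || !nrow(as.data.table(recon))) return(0)
  tk <- match_segments(truth, recon, tol = tol)
  sw_score(tk$tokens_recon, tk$tokens_truth, match = match_score,
           mismatch = -match_score, gap = 0) / (m * match_score)
}

#' Mean Reconstruction Accuracy over repetitions
#'
#' `mean_RA = (1/N) * sum_k ( sum_i RA_ik / n_k )` where the inner sum runs
#' over the strains of repetition k and `n_k` counts non-empty
#' reconstructions in repetition k (a repetition with `n_k = 0` contributes
#' 0, with a warning).
#'
#' @param ra_list list of numeric vectors, one per repetition: the per-
#'   strain RA values (include 0 entries for strains with empty
#'   reconstructions).
#' @param n_nonempty optional integer vector of per-repetition non-empty
#'   counts; defaults to the number of RA values > 0 plus matched empties
#'   counted as reconstructions (i.e. `sum(ra > 0)`).
#' @return the mean RA.
#' @export
mean_ra <- function(ra_list, n_nonempty = NULL) {
  N <- length(ra_list)
  if (N < 1L) stopf("need at least one repetition")
  if (is.null(n_nonempty)) n_nonempty <- vapply(ra_list, function(x) sum(x > 0), numeric(1))
  terms <- vapply(seq_len(N), function(k) {
    if (n_nonempty[k] == 0) { warnf("repetition %d has no non-empty reconstruction", k); 0 }
    else sum(ra_list[[k]]) / n_nonempty[k]
  }, numeric(1))
  sum(terms) / N
}

# Pair-level distance between two breakpoint pairs on the same canonical
# reference pair: max of the two per-side coordinate differences (Inf when
# the reference pairs differ).
.pair_dist <- function(r1a, p1a, r2a, p2a, r1b, p1b, r2b, p2b) {
  ifelse(r1a == r1b & r2a == r2b, pmax(abs(p1a - p1b), abs(p2a - p2b)), Inf)
}

.canonical_pairs <- function(bp) {
  bp <- as.data.table(bp)
  swap <- bp$ref1 > bp$ref2
  data.table(ref1 = ifelse(swap, bp$ref2, bp$ref1),
             pos1 = ifelse(swap, bp$pos2, bp$pos1),
             ref2 = ifelse(swap, bp$ref1, bp$ref2),
             pos2 = ifelse(swap, bp$pos1, bp$pos2))
}

# Greedy nearest-first 1-to-1 matching between two breakpoint pair tables.
# Returns logical vector over `calls`: matched to an unclaimed truth pair.
.match_pairs <- function(truth, calls, tol) {
  tr <- .canonical_pairs(truth); ca <- .canonical_pairs(calls)
  matched_call <- logical(nrow(ca)); used_truth <- logical(nrow(tr))
  if (!nrow(ca) || !nrow(tr)) return(matched_call)
  cand <- list()
  for (i in seq_len(nrow(ca))) {
    d <- .pair_dist(ca$ref1[i], ca$pos1[i], ca$ref2[i], ca$pos2[i],
                    tr$ref1, tr$pos1, tr$ref2, tr$pos2)
    ok <- which(d <= tol)
    for (j in ok) cand[[length(cand) + 1L]] <- c(i, j, d[j])
  }
  if (length(cand)) {
    cd <- do.call(rbind, cand)
    cd <- cd[order(cd[, 3], cd[, 1], cd[, 2]), , drop = FALSE]
    for (k in seq_len(nrow(cd))) {
      i <- cd[k, 1]; j <- cd[k, 2]
      if (matched_call[i] || used_truth[j]) next
      matched_call[i] <- TRUE; used_truth[j] <- TRUE
    }
  }
  matched_call
}

#' Detection Rate of transferred segments
#'
#' A transferred segment is acceptably recovered when *both* of its
#' boundary breakpoint pairs are matched by calls within `tol` bp (each
#' side of a pair must be within `tol`).
#'
#' @param truth_breakpoints truth junction table (columns ref1, pos1, ref2,
#'   pos2 plus the transferred-segment labels `seg_up`/`seg_dn` of the
#'   junction's flanks, as produced by [plant_hgt_events()]).
#' @param calls called breakpoint table (ref1, pos1, ref2, pos2).
#' @param tol tolerance in bp (default 20).
#' @return fraction of transferred segments recovered.
#' @export
detection_rate <- function(truth_breakpoints, calls, tol = 20L) {
  tb <- as.data.table(truth_breakpoints)
  if (!nrow(tb)) stopf("truth must contain at least one transferred segment")
  matched_truth <- .match_pairs(as.data.table(calls), tb, tol)
  labs <- unique(stats::na.omit(c(tb$seg_up, tb$seg_dn)))
  ok <- vapply(labs, function(lab) {
    rows <- which((!is.na(tb$seg_up) & tb$seg_up == lab) |
                    (!is.na(tb$seg_dn) & tb$seg_dn == lab))
    all(matched_truth[rows])
  }, logical(1))
  mean(ok)
}

#' Breakpoint sensitivity and false discovery rate
#'
#' Calls are matched 1-to-1 (nearest-first) to truth breakpoint pairs; a
#' call farther than `tol` bp (on either side) from every unclaimed truth
#' pair is a false detection. Sensitivity = matched truth / all truth;
#' FDR = false calls / all calls (0 with a flag when there are no calls).
#'
#' @param truth_breakpoints,calls breakpoint pair tables (ref1, pos1, ref2,
#'   pos2).
#' @param tol tolerance in bp (default 20).
#' @return list: sensitivity, fdr, n_truth, n_calls, n_true_calls,
#'   fdr_defined.
#' @export
breakpoint_sensitivity_fdr <- function(truth_breakpoints, calls, tol = 20L) {
  tb <- as.data.table(truth_breakpoints); ca <- as.data.table(calls)
  matched_truth <- .match_pairs(ca, tb, tol)   # per truth pair
  matched_call <- .match_pairs(tb, ca, tol)    # per call
  n_truth <- nrow(tb); n_calls <- nrow(ca)
  sens <- if (n_truth) sum(matched_truth) / n_truth else NA_real_
  fdr_defined <- n_calls > 0L
  fdr <- if (fdr_defined) sum(!matched_call) / n_calls else 0
  list(sensitivity = sens, fdr = fdr, n_truth = n_truth, n_calls = n_calls,
       n_true_calls = sum(matched_call), fdr_defined = fdr_defined)
}

#' Evaluate a reconstruction against the simulator truth
#'
#' Convenience wrapper: per-receptor RA (best reconstructed strain per
#' receptor), detection rate over transferred segments, and breakpoint
#' sensitivity/FDR.
#'
#' @param truth_segments,truth_breakpoints truth tables from
#'   [plant_hgt_events()].
#' @param structure reconstructed structure table from
#'   [reconstruct_strains()].
#' @param calls called breakpoints.
#' @param tol tolerance (bp).
#' @return list with `ra` (named per true strain), `detection_rate`,
#'   `sensitivity`, `fdr`.
#' @export
evaluate_reconstruction <- function(truth_segments, truth_breakpoints,
                                    structure, calls, tol = 20L) {
  ts <- as.data.table(truth_segments)
  st <- as.data.table(structure)
  ras <- vapply(unique(ts$strain_id), function(sid) {
    truth <- ts[strain_id == sid][order(rank)]
    rec_ref <- truth$source_ref[1]
    if (!nrow(st)) return(0)
    cand_ids <- unique(st[source_ref == rec_ref & rank == 1, strain_id])
    if (!length(cand_ids)) return(0)
    max(vapply(cand_ids, function(cid)
      reconstruction_accuracy(truth, st[strain_id == cid][order(rank)], tol = tol),
      numeric(1)))
  }, numeric(1))
  dr <- detection_rate(truth_breakpoints, calls, tol = tol)
  sf <- breakpoint_sensitivity_fdr(truth_breakpoints, calls, tol = tol)
  list(ra = ras, detection_rate = dr, sensitivity = sf$sensitivity, fdr = sf$fdr)
}
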