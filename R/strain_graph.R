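#' Partition references into segments at called breakpoints
#'
#' Cuts every reference carrying at least one (precise) breakend at all its
#' breakend coordinates (coordinates closer than `merge_tol` are merged).
#' References hosting an *insertion locus* — an `L`-direction and an
#' `R`-direction breakend at (nearly) the same position, i.e. a donor path
#' that leaves and returns — are classified as receptors, and their first
#' and last segments become the strain start (`b_i`) and end (`t_i`)
#' segments. Segments shorter than `min_segment_len` are merged into a
#' neighbour; segments with mean coverage below `min_segment_cov` are
#' dropped (uncovered donor flanks).
#'
#' @param breakpoints table from [call_breakpoints()] (precise calls are
#'   used).
#' @param ref_lengths named vector of reference lengths.
#' @param coverage a [coverage_profile()].
#' @param min_segment_len minimum segment length in bp (default 50).
#' @param min_segment_cov minimum mean depth for a segment to be kept.
#' @param receptors optional character vector overriding receptor
#'   identification.
#' @param locus_tol maximum distance between the L and R breakends of one
#'   insertion locus (bp).
#' @param merge_tol breakend coordinates within this distance collapse to
#'   one cut (bp).
#' @return a list with `segments` (seg_id, ref, start, end, role, cov,
#'   copy_est, target) and `receptors` (i, ref); roles are
#'   `receptor_first`, `receptor_internal`, `receptor_last`, `donor`.
#' @export
partition_references <- function(breakpoints, ref_lengths, coverage,
                                 min_segment_len = 50L, min_segment_cov = 0.5,
                                 receptors = NULL, locus_tol = 50L,
                                 merge_tol = 20L) {
  bp <- as.data.table(breakpoints)[precise == TRUE]
  if (!nrow(bp)) {
    return(list(segments = .empty_segments(), receptors = data.table(i = integer(0), ref = character(0))))
  }
  ends <- rbind(bp[, .(ref = ref1, pos = pos1, dir = dir1)],
                bp[, .(ref = ref2, pos = pos2, dir = dir2)])
  bad <- ends[pos < 0 | pos > ref_lengths[ref]]
  if (nrow(bad))
    stopf("breakpoint at %d outside reference %s", bad$pos[1], bad$ref[1])
  missing_ref <- setdiff(unique(ends$ref), names(ref_lengths))
  if (length(missing_ref))
    stopf("breakpoint on reference '%s' absent from the reference set", missing_ref[1])
  # receptor identification: an L and an R breakend at ~the same position
  if (is.null(receptors)) {
    receptors <- character(0)
    for (r in unique(ends$ref)) {
      pl <- ends[ref == r & dir == "L", pos]; pr <- ends[ref == r & dir == "R", pos]
      if (length(pl) && length(pr) &&
          any(vapply(pl, function(p) any(abs(pr - p) <= locus_tol), logical(1))))
        receptors <- c(receptors, r)
    }
  }
  segs <- list()
  for (r in unique(ends$ref)) {
    cuts <- sort(unique(ends[ref == r, pos]))
    # merge cuts closer than merge_tol
    grp <- cumsum(c(TRUE, diff(cuts) > merge_tol))
    cuts <- as.integer(round(tapply(cuts, grp, mean)))
    bounds <- unique(c(0L, cuts, ref_lengths[[r]]))
    bounds <- sort(bounds)
    s <- data.table(ref = r, start = head(bounds, -1L), end = tail(bounds, -1L))
    # merge short segments into their left neighbour (right for the first)
    while (nrow(s) > 1L && any(s$end - s$start < min_segment_len)) {
      i <- which(s$end - s$start < min_segment_len)[1]
      if (i == 1L) { s$start[2] <- s$start[1]; s <- s[-1] }
      else { s$end[i - 1L] <- s$end[i]; s <- s[-i] }
    }
    segs[[r]] <- s
  }
  segs <- rbindlist(segs)
  segs[, cov := vapply(seq_len(.N), function(i)
    interval_coverage(coverage, ref[i], start[i], end[i]), numeric(1))]
  segs <- segs[cov >= min_segment_cov]
  if (!nrow(segs))
    return(list(segments = .empty_segments(), receptors = data.table(i = integer(0), ref = character(0))))
  segs[, role := ifelse(ref %in% receptors, "receptor_internal", "donor")]
  for (r in receptors) {
    idx <- which(segs$ref == r)
    if (!length(idx)) next
    segs$role[idx[1]] <- "receptor_first"
    segs$role[idx[length(idx)]] <- "receptor_last"
  }
  segs[, seg_id := .I]
  setcolorder(segs, c("seg_id", "ref", "start", "end", "role", "cov"))
  rec <- data.table(i = seq_along(intersect(receptors, segs$ref)),
                    ref = intersect(receptors, segs$ref))
  list(segments = segs, receptors = rec)
}

.empty_segments <- function() {
  data.table(seg_id = integer(0), ref = character(0), start = integer(0),
             end = integer(0), role = character(0), cov = numeric(0),
             copy_est = numeric(0), target = integer(0))
}

#' Estimate initial segment copy numbers from coverage
#'
#' `c(v) = cov(v) / cov(r)` where `cov(r)` is the length-weighted mean depth
#' over the *retained* segments of the parent reference (so references that
#' only appear through their covered, HGT-involved portion are normalised by
#' that portion). Integer targets are `t(v) = max(1, round(c(v)))`.
#'
#' @param segments segment table from [partition_references()].
#' @param coverage a [coverage_profile()] (unused when `cov` is already
#'   present on `segments`; kept for the module contract).
#' @return the segment table with `copy_est` and `target` columns.
#' @export
estimate_copy_numbers <- function(segments, coverage = NULL) {
  segs <- as.data.table(segments)
  if (!nrow(segs)) return(segs)
  if (!"cov" %in% names(segs)) {
    segs[, cov := vapply(seq_len(.N), function(i)
      interval_coverage(coverage, ref[i], start[i], end[i]), numeric(1))]
  }
  segs[, ref_cov := sum(cov * (end - start)) / sum(end - start), by = ref]
  drop <- unique(segs[ref_cov <= 0, ref])
  if (length(drop)) {
    warnf("reference(s) with zero coverage excluded: %s", paste(drop, collapse = ", "))
    segs <- segs[!ref %in% drop]
  }
  segs[, copy_est := cov / ref_cov]
  segs[, target := pmax(1L, as.integer(round(copy_est)))]
  segs[, ref_cov := NULL]
  segs[]
}

#' Build the bidirected strain graph
#'
#' One vertex per segment; edges attach to segment *ends* (`l`/`r`): a
#' breakend with direction `L` at position p attaches the right end of the
#' segment ending at p, direction `R` the left end of the segment starting
#' at p. Observed junction edges come from precise breakpoint calls;
#' reference-adjacency edges join consecutive retained segments of every
#' reference that carries a breakpoint. Edge copy numbers are initialised to
#' `max(1, round(min incident copy_est))`; adjacency edges without read
#' support get lower bound 0 (the balancing step decides whether the plain
#' reference path is traversed), observed edges lower bound 1.
#'
#' @param partition result of [partition_references()] after
#'   [estimate_copy_numbers()] (i.e. `segments` carries `copy_est`).
#' @param breakpoints table from [call_breakpoints()].
#' @param boundary_tol maximum distance between a called position and a
#'   segment boundary (bp).
#' @return an object of class `strain_graph`: list with `segments`, `edges`
#'   (edge_id, seg1, end1, seg2, end2, kind, support, target, copy, lb) and
#'   `receptors` (i, ref, b_seg, t_seg).
#' @export
build_strain_graph <- function(partition, breakpoints, boundary_tol = 25L) {
  segs <- as.data.table(partition$segments)
  bp <- as.data.table(breakpoints)[precise == TRUE]
  edges <- list()
  find_attach <- function(ref_, pos_, dir_) {
    cand <- segs[ref == ref_]
    if (!nrow(cand)) return(NULL)
    if (dir_ == "L") {
      d <- abs(cand$end - pos_)
      i <- which.min(d)
      if (d[i] > boundary_tol) return(NULL)
      list(seg = cand$seg_id[i], end = "r")
    } else {
      d <- abs(cand$start - pos_)
      i <- which.min(d)
      if (d[i] > boundary_tol) return(NULL)
      list(seg = cand$seg_id[i], end = "l")
    }
  }
  n_skip <- 0L
  for (i in seq_len(nrow(bp))) {
    a <- find_attach(bp$ref1[i], bp$pos1[i], bp$dir1[i])
    b <- find_attach(bp$ref2[i], bp$pos2[i], bp$dir2[i])
    if (is.null(a) || is.null(b)) { n_skip <- n_skip + 1L; next }
    est <- min(segs[seg_id == a$seg, copy_est], segs[seg_id == b$seg, copy_est])
    edges[[length(edges) + 1L]] <- data.table(
      seg1 = a$seg, end1 = a$end, seg2 = b$seg, end2 = b$end,
      kind = "observed", support = bp$n_junction[i] + bp$n_split[i],
      target = max(1L, as.integer(round(est))), lb = 1L)
  }
  if (n_skip)
    message(sprintf("build_strain_graph: %d breakpoint(s) without matching segment boundary skipped", n_skip))
  # reference adjacency between consecutive retained segments
  for (r in unique(segs$ref)) {
    sub <- segs[ref == r][order(start)]
    if (nrow(sub) < 2L) next
    for (j in seq_len(nrow(sub) - 1L)) {
      if (sub$end[j] != sub$start[j + 1L]) next
      est <- min(sub$copy_est[j], sub$copy_est[j + 1L])
      edges[[length(edges) + 1L]] <- data.table(
        seg1 = sub$seg_id[j], end1 = "r", seg2 = sub$seg_id[j + 1L], end2 = "l",
        kind = "adjacency", support = 0L,
        target = max(1L, as.integer(round(est))), lb = 0L)
    }
  }
  edges <- if (length(edges)) rbindlist(edges) else
    data.table(seg1 = integer(0), end1 = character(0), seg2 = integer(0),
               end2 = character(0), kind = character(0), support = integer(0),
               target = integer(0), lb = integer(0))
  edges[, copy := target]
  edges[, edge_id := .I]
  setcolorder(edges, c("edge_id", "seg1", "end1", "seg2", "end2", "kind",
                       "support", "target", "copy", "lb"))
  rec <- as.data.table(partition$receptors)
  if (nrow(rec)) {
    rec[, b_seg := vapply(ref, function(r) segs[ref == r][order(start)][1, seg_id], integer(1))]
    rec[, t_seg := vapply(ref, function(r) segs[ref == r][order(-start)][1, seg_id], integer(1))]
  } else {
    rec <- data.table(i = integer(0), ref = character(0), b_seg = integer(0),
                      t_seg = integer(0))
  }
  segs[, copy := NA_integer_]
  structure(list(segments = segs, edges = edges, receptors = rec),
            class = "strain_graph")
}

#' @export
print.strain_graph <- function(x, ...) {
  cat(sprintf("strain_graph: %d segments, %d edges (%s), %d receptor(s)\n",
              nrow(x$segments), nrow(x$edges),
              paste(sprintf("%d %s", table(x$edges$kind),
                            names(table(x$edges$kind))), collapse = ", "),
              nrow(x$receptors)))
  invisible(x)
}

#' Insert dummy and chain edges to close strain paths into one circuit
#'
#' For each receptor i: a dummy back-edge `t_i -> b_i` with copy number
#' `c(b_i) - 1` (omitted when that is 0), chain edges `t_i -> b_{i+1}` with
#' copy 1 and the wrap-around `t_k -> b_1` with copy 1. `c(b_i) = c(t_i)` is
#' enforced by rounding the mean of the two estimates (at least 1).
#'
#' @param graph a `strain_graph`.
#' @return the graph with dummy/chain edges appended.
#' @export
insert_dummy_edges <- function(graph) {
  rec <- graph$receptors
  k <- nrow(rec)
  if (k == 0L) return(graph)
  segs <- graph$segments
  new_edges <- list()
  for (i in seq_len(k)) {
    cb <- max(1L, as.integer(round(mean(c(segs[seg_id == rec$b_seg[i], copy_est],
                                          segs[seg_id == rec$t_seg[i], copy_est])))))
    graph$segments[seg_id %in% c(rec$b_seg[i], rec$t_seg[i]), target := cb]
    if (cb - 1L > 0L)
      new_edges[[length(new_edges) + 1L]] <- data.table(
        seg1 = rec$t_seg[i], end1 = "r", seg2 = rec$b_seg[i], end2 = "l",
        kind = "dummy", support = 0L, target = cb - 1L, copy = cb - 1L, lb = 0L)
    nxt <- if (i == k) 1L else i + 1L
    new_edges[[length(new_edges) + 1L]] <- data.table(
      seg1 = rec$t_seg[i], end1 = "r", seg2 = rec$b_seg[nxt], end2 = "l",
      kind = "chain", support = 0L, target = 1L, copy = 1L, lb = 1L)
  }
  ne <- rbindlist(new_edges)
  ne[, edge_id := nrow(graph$edges) + .I]
  setcolorder(ne, names(graph$edges))
  graph$edges <- rbind(graph$edges, ne)
  graph
}

# Undirected port connectivity: which segments are connected to any b/t
# segment through edges (segments connect their own two ends internally).
.segment_components <- function(graph) {
  segs <- graph$segments$seg_id
  parent <- setNames(segs, as.character(segs))
  find <- function(x) {
    while (parent[[as.character(x)]] != x) x <- parent[[as.character(x)]]
    x
  }
  if (nrow(graph$edges)) for (i in seq_len(nrow(graph$edges))) {
    a <- find(graph$edges$seg1[i]); b <- find(graph$edges$seg2[i])
    if (a != b) parent[[as.character(a)]] <- b
  }
  vapply(segs, find, numeric(1))
}

#' Repair graph connectivity
#'
#' Removes segments that are not connected to any receptor start/end
#' segment, and gives every remaining segment end that lacks an incident
#' edge a copy-1 repair edge: along the reference to the adjacent retained
#' segment when one exists, otherwise a single bridging edge to the nearest
#' segment boundary on the component's receptor reference (minimum number of
#' inserted edges). Idempotent.
#'
#' @param graph a `strain_graph` (after [insert_dummy_edges()]).
#' @return the repaired graph.
#' @export
repair_connectivity <- function(graph) {
  if (!nrow(graph$segments)) return(graph)
  comp <- .segment_components(graph)
  bt <- unique(c(graph$receptors$b_seg, graph$receptors$t_seg))
  keep_comp <- unique(comp[match(bt, graph$segments$seg_id)])
  drop <- graph$segments$seg_id[!comp %in% keep_comp]
  if (length(drop)) {
    message(sprintf("repair_connectivity: removed %d segment(s) unreachable from any receptor", length(drop)))
    graph$segments <- graph$segments[!seg_id %in% drop]
    graph$edges <- graph$edges[!(seg1 %in% drop | seg2 %in% drop)]
  }
  segs <- graph$segments
  deg <- function(seg, end) {
    sum((graph$edges$seg1 == seg & graph$edges$end1 == end) +
          (graph$edges$seg2 == seg & graph$edges$end2 == end))
  }
  new_edges <- list()
  for (i in seq_len(nrow(segs))) {
    for (e in c("l", "r")) {
      if (deg(segs$seg_id[i], e) > 0L) next
      # receptor outer ends are the circuit boundary handled by dummy edges
      if ((segs$role[i] == "receptor_first" && e == "l") ||
          (segs$role[i] == "receptor_last" && e == "r")) next
      # prefer the neighbouring retained segment on the same reference
      same <- segs[ref == segs$ref[i]]
      tgt <- NULL
      if (e == "r") {
        nxt <- same[start >= segs$end[i]][order(start)]
        if (nrow(nxt)) tgt <- list(seg = nxt$seg_id[1], end = "l")
      } else {
        prv <- same[end <= segs$start[i]][order(-end)]
        if (nrow(prv)) tgt <- list(seg = prv$seg_id[1], end = "r")
      }
      if (is.null(tgt)) {
        # bridge to the nearest boundary on a receptor reference
        rsegs <- segs[ref %in% graph$receptors$ref & seg_id != segs$seg_id[i]]
        if (!nrow(rsegs)) next
        j <- which.min(abs(rsegs$start - segs$start[i]))
        tgt <- list(seg = rsegs$seg_id[j], end = if (e == "r") "l" else "r")
      }
      new_edges[[length(new_edges) + 1L]] <- data.table(
        seg1 = segs$seg_id[i], end1 = e, seg2 = tgt$seg, end2 = tgt$end,
        kind = "repair", support = 0L, target = 1L, copy = 1L, lb = 0L)
    }
  }
  if (length(new_edges)) {
    ne <- rbindlist(new_edges)
    ne[, edge_id := max(graph$edges$edge_id, 0L) + .I]
    setcolorder(ne, names(graph$edges))
    graph$edges <- rbind(graph$edges, ne)
    message(sprintf("repair_connectivity: inserted %d repair edge(s)", nrow(ne)))
  }
  graph
}
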