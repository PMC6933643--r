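# Copy-number balancing and Eulerian strain reconstruction.
#
# The balance program: choose integer copies c(e) for edges and c(u) for
# segments so that at every segment the edge copies attached to its left
# end, the edge copies attached to its right end, and c(u) coincide
# (the in/out-copy balance of the bidirected graph), minimising
# sum |c(u) - t(u)| + sum |c(e) - t(e)| against the coverage-derived
# targets. Solved exactly by depth-first search with interval propagation
# and cost bounding; a greedy repair fallback takes over past a search-node
# cap (large instances).

# endpoints: 2-column integer matrix per edge row: (vertex index, side 1=l/2=r)
.balance_search <- function(lb_e, ub_e, t_e, vlb, t_v, ep1, ep2, s1, s2,
                            node_cap = 2e6) {
  n_e <- length(lb_e); n_v <- length(vlb)
  # per-vertex/side assigned sums and remaining min/max contributions
  sumA <- matrix(0L, n_v, 2)
  minR <- matrix(0L, n_v, 2); maxR <- matrix(0L, n_v, 2)
  for (e in seq_len(n_e)) {
    minR[ep1[e], s1[e]] <- minR[ep1[e], s1[e]] + lb_e[e]
    maxR[ep1[e], s1[e]] <- maxR[ep1[e], s1[e]] + ub_e[e]
    minR[ep2[e], s2[e]] <- minR[ep2[e], s2[e]] + lb_e[e]
    maxR[ep2[e], s2[e]] <- maxR[ep2[e], s2[e]] + ub_e[e]
  }
  val <- rep(NA_integer_, n_e)
  best <- list(cost = Inf, val = NULL, cv = NULL)
  nodes <- 0L; capped <- FALSE
  vcost_lb <- function() {
    tot <- 0
    for (v in seq_len(n_v)) {
      lo <- max(sumA[v, 1] + minR[v, 1], sumA[v, 2] + minR[v, 2], vlb[v])
      hi <- min(sumA[v, 1] + maxR[v, 1], sumA[v, 2] + maxR[v, 2])
      if (lo > hi) return(Inf)
      tot <- tot + max(0, t_v[v] - hi, lo - t_v[v])
    }
    tot
  }
  apply_edge <- function(e, x, sign) {
    for (k in 1:2) {
      v <- if (k == 1) ep1[e] else ep2[e]
      s <- if (k == 1) s1[e] else s2[e]
      sumA[v, s] <<- sumA[v, s] + sign * x
      minR[v, s] <<- minR[v, s] - sign * lb_e[e]
      maxR[v, s] <<- maxR[v, s] - sign * ub_e[e]
    }
  }
  rec <- function(e, cost_edges) {
    if (nodes > node_cap) { capped <<- TRUE; return() }
    if (e > n_e) {
      cv <- integer(n_v); tot <- cost_edges
      for (v in seq_len(n_v)) {
        if (sumA[v, 1] != sumA[v, 2] || sumA[v, 1] < vlb[v]) return()
        cv[v] <- sumA[v, 1]
        tot <- tot + abs(cv[v] - t_v[v])
      }
      if (tot < best$cost) best <<- list(cost = tot, val = val, cv = cv)
      return()
    }
    vals <- lb_e[e]:ub_e[e]
    vals <- vals[order(abs(vals - t_e[e]), vals)]
    for (x in vals) {
      nodes <<- nodes + 1L
      ce <- cost_edges + abs(x - t_e[e])
      if (ce >= best$cost) next
      val[e] <<- x
      apply_edge(e, x, 1L)
      lbnd <- ce + vcost_lb()
      if (lbnd < best$cost) rec(e + 1L, ce)
      apply_edge(e, x, -1L)
      val[e] <<- NA_integer_
    }
  }
  if (n_e == 0L) {
    cv <- pmax(vlb, 0L)
    # no edges: every vertex must have copy 0 (no attachments)
    feas <- all(vlb == 0L)
    return(list(cost = if (feas) sum(t_v) else Inf,
                val = integer(0), cv = rep(0L, n_v), exact = TRUE, nodes = 0L))
  }
  rec(1L, 0)
  list(cost = best$cost, val = best$val, cv = best$cv, exact = !capped,
       nodes = nodes)
}

# Greedy fallback: start at targets, repair imbalances by cheapest unit moves.
.balance_greedy <- function(lb_e, ub_e, t_e, vlb, t_v, ep1, ep2, s1, s2,
                            max_iter = 5000L) {
  n_v <- length(vlb)
  x <- pmax(lb_e, pmin(ub_e, t_e))
  sums <- function(x) {
    m <- matrix(0L, n_v, 2)
    for (e in seq_along(x)) {
      m[ep1[e], s1[e]] <- m[ep1[e], s1[e]] + x[e]
      m[ep2[e], s2[e]] <- m[ep2[e], s2[e]] + x[e]
    }
    m
  }
  imb <- function(m) sum(abs(m[, 1] - m[, 2])) + sum(pmax(0L, vlb - m[, 1]))
  m <- sums(x)
  for (it in seq_len(max_iter)) {
    cur <- imb(m)
    if (cur == 0L) break
    improved <- FALSE
    for (e in seq_along(x)) for (dx in c(-1L, 1L)) {
      nx <- x[e] + dx
      if (nx < lb_e[e] || nx > ub_e[e]) next
      x2 <- x; x2[e] <- nx
      m2 <- sums(x2)
      if (imb(m2) < cur) { x <- x2; m <- m2; improved <- TRUE; break }
    }
    if (!improved) break
  }
  cv <- pmax(m[, 1], vlb)
  list(cost = sum(abs(x - t_e)) + sum(abs(cv - t_v)), val = x, cv = cv,
       exact = FALSE, nodes = NA_integer_)
}

#' Balance segment and edge copy numbers by integer programming
#'
#' Solves the degree-balance program exactly (branch-and-bound with
#' interval propagation): integer copies on edges within their bounds,
#' segment copies equal to the attached copy sum on both ends, objective
#' `sum |c - t|` over segments and edges. Beyond `node_cap` search nodes a
#' greedy repair heuristic is used and flagged. Zero-copy edges and
#' segments are removed from the balanced graph.
#'
#' @param graph a `strain_graph` (after dummy insertion / repair).
#' @param copy_ub upper bound on copies (default `max(4, 4 * max target)`).
#' @param node_cap search-node cap before falling back to the heuristic.
#' @return the graph with integer `copy` set on segments and edges, plus a
#'   `solver` element (objective, exact flag, nodes).
#' @export
balance_strain_graph <- function(graph, copy_ub = NULL, node_cap = 2e6) {
  segs <- graph$segments; edges <- graph$edges
  if (!nrow(segs)) {
    graph$solver <- list(objective = 0, exact = TRUE, nodes = 0L)
    return(graph)
  }
  vid <- segs$seg_id
  t_v <- segs$target
  if (is.null(t_v) || any(is.na(t_v))) t_v <- pmax(1L, as.integer(round(segs$copy_est)))
  bt <- unique(c(graph$receptors$b_seg, graph$receptors$t_seg))
  vlb <- ifelse(vid %in% bt, 1L, 0L)
  ub <- copy_ub %||% max(4L, 4L * max(t_v, edges$target, 1L))
  res <- if (nrow(edges)) {
    ep1 <- match(edges$seg1, vid); ep2 <- match(edges$seg2, vid)
    s1 <- ifelse(edges$end1 == "l", 1L, 2L); s2 <- ifelse(edges$end2 == "l", 1L, 2L)
    r <- .balance_search(edges$lb, pmin(rep(ub, nrow(edges)), ub), edges$target,
                         vlb, t_v, ep1, ep2, s1, s2, node_cap = node_cap)
    if (!is.finite(r$cost) || (!r$exact && is.null(r$val)))
      r <- .balance_greedy(edges$lb, rep(ub, nrow(edges)), edges$target,
                           vlb, t_v, ep1, ep2, s1, s2)
    if (!r$exact && r$cost == Inf)
      stopf("balance infeasible: no integer circulation satisfies the bounds")
    r
  } else list(cost = 0, val = integer(0), cv = rep(0L, nrow(segs)), exact = TRUE,
              nodes = 0L)
  if (!is.finite(res$cost))
    stopf("balance infeasible: no integer circulation satisfies the bounds")
  graph$edges$copy <- res$val
  graph$segments$copy <- res$cv
  graph$edges <- graph$edges[copy > 0L]
  graph$segments <- graph$segments[copy > 0L]
  graph$solver <- list(objective = res$cost, exact = res$exact, nodes = res$nodes)
  graph
}

#' Verify the degree-balance property
#'
#' @param graph a `strain_graph` with copies set.
#' @return list with `balanced` (logical) and `violations` (one row per
#'   segment failing `c_left = c(u) = c_right`).
#' @export
verify_balance <- function(graph) {
  segs <- graph$segments
  if (!nrow(segs)) return(list(balanced = TRUE, violations = data.table()))
  e <- graph$edges
  csum <- function(seg, end)
    sum(e$copy[(e$seg1 == seg & e$end1 == end)]) +
    sum(e$copy[(e$seg2 == seg & e$end2 == end)])
  v <- data.table(seg_id = segs$seg_id,
                  c_left = vapply(segs$seg_id, csum, numeric(1), end = "l"),
                  c_right = vapply(segs$seg_id, csum, numeric(1), end = "r"),
                  copy = segs$copy)
  viol <- v[c_left != copy | c_right != copy]
  list(balanced = nrow(viol) == 0L, violations = viol)
}

# kind preference for deterministic traversal: observed junctions first,
# artificial circuit-closing edges last (dummy back-edges before chain edges
# so all copies of one strain complete before moving to the next receptor).
.kind_rank <- c(observed = 1L, adjacency = 2L, repair = 3L, dummy = 4L,
                chain = 5L)

#' Eulerian circuit of the balanced strain graph
#'
#' Expands every edge to its copy-number multiplicity and finds a closed
#' walk that enters each segment through one end and leaves through the
#' other, traversing every edge unit exactly once (so each segment is
#' visited `c(u)` times). The walk is grown as a greedy trail from the
#' first receptor's start segment, preferring observed junction edges over
#' adjacency, repair, dummy and chain edges (ties by partner coordinate);
#' leftover balanced sub-curves are spliced in at shared segments,
#' reversed when their reading direction disagrees. A visit entered at the
#' left end is a `+` traversal, at the right end `-`.
#'
#' @param graph a balanced `strain_graph` ([verify_balance()] must hold).
#' @return `data.table` circuit: step, seg_id, orientation, in_edge,
#'   in_kind (edge traversed to arrive at this visit).
#' @export
eulerian_circuit <- function(graph) {
  vb <- verify_balance(graph)
  if (!vb$balanced)
    stopf("eulerian_circuit: graph is not balanced (%d violation(s))", nrow(vb$violations))
  edges <- graph$edges[copy > 0L]
  segs <- graph$segments
  if (!nrow(edges)) stopf("eulerian_circuit: no edges to traverse")
  comp <- .segment_components(graph)
  if (length(unique(comp[match(unique(c(edges$seg1, edges$seg2)), segs$seg_id)])) > 1L)
    stopf("eulerian_circuit: graph is disconnected")
  # expand to units; each unit has two endpoints (rows of `ends`)
  units <- edges[rep(seq_len(.N), copy)]
  units[, unit := .I]
  ends <- rbind(units[, .(unit, ep = 1L, seg = seg1, end = end1, kind, edge_id)],
                units[, .(unit, ep = 2L, seg = seg2, end = end2, kind, edge_id)])
  ends[, partner_seg := ifelse(ep == 1L, units$seg2[unit], units$seg1[unit])]
  ends[, rank := .kind_rank[kind]]
  ends <- merge(ends, segs[, .(partner_seg = seg_id, pstart = start)],
                by = "partner_seg", sort = FALSE)
  ends[, idx := .I]
  other <- integer(nrow(ends))  # endpoint idx -> the unit's other endpoint
  o1 <- ends[ep == 1L][order(unit)]; o2 <- ends[ep == 2L][order(unit)]
  other[o1$idx] <- o2$idx; other[o2$idx] <- o1$idx
  # per-port preference-ordered endpoint lists
  ends[, port := paste0(seg, ".", end)]
  port_idx <- split(ends[order(rank, pstart, unit, ep), idx],
                    ends[order(rank, pstart, unit, ep), port])
  used <- logical(max(units$unit))
  pick <- function(seg, end) {
    cand <- port_idx[[paste0(seg, ".", end)]]
    if (is.null(cand)) return(NA_integer_)
    cand <- cand[!used[ends$unit[cand]]]
    if (!length(cand)) NA_integer_ else cand[1]
  }
  flip_end <- function(e) ifelse(e == "l", "r", "l")
  # grow a trail from (seg, enter_end); steps are (unit endpoint arrived at)
  trace <- function(seg, enter_end) {
    steps <- integer(0)
    repeat {
      dep <- pick(seg, flip_end(enter_end))
      if (is.na(dep)) break
      used[ends$unit[dep]] <<- TRUE
      arr <- other[dep]
      steps <- c(steps, arr)
      seg <- ends$seg[arr]; enter_end <- ends$end[arr]
    }
    steps
  }
  # start: an artificial (chain/dummy) unit entering b_1 forward, if any
  start_arr <- NA_integer_
  if (nrow(graph$receptors)) {
    b1 <- graph$receptors$b_seg[1]
    cand <- ends[seg == b1 & end == "l" & kind %in% c("chain", "dummy"), idx]
    if (length(cand)) start_arr <- cand[1]
  }
  if (is.na(start_arr)) start_arr <- 1L
  used[ends$unit[start_arr]] <- TRUE
  walk <- c(start_arr,
            trace(ends$seg[start_arr], ends$end[start_arr]))
  # splice leftover balanced sub-curves at shared segments
  guard <- 0L
  while (any(!used)) {
    guard <- guard + 1L
    if (guard > length(used) + 10L)
      stopf("eulerian_circuit: graph is disconnected at unit level")
    spliced <- FALSE
    for (j in seq_along(walk)) {
      u <- ends$seg[walk[j]]; entry <- ends$end[walk[j]]
      dep <- pick(u, flip_end(entry))
      if (is.na(dep)) next
      sub <- trace(u, entry)
      if (!length(sub)) next
      last <- sub[length(sub)]
      if (ends$seg[last] != u || ends$end[last] != entry)
        stopf("internal error: sub-curve did not close at its anchor segment")
      walk <- append(walk, sub, after = j)
      spliced <- TRUE
      break
    }
    if (!spliced) stopf("eulerian_circuit: graph is disconnected at unit level")
  }
  data.table(step = seq_along(walk),
             seg_id = ends$seg[walk],
             orientation = ifelse(ends$end[walk] == "l", "+", "-"),
             in_edge = ends$edge_id[walk],
             in_kind = ends$kind[walk])
}

.reverse_circuit <- function(circuit) {
  m <- nrow(circuit)
  idx <- rev(seq_len(m))
  out <- circuit[idx]
  out[, orientation := ifelse(orientation == "+", "-", "+")]
  # edge into reversed visit j is the edge out of it in the old direction,
  # i.e. the in_edge of the old successor visit
  old_next <- idx %% m + 1L
  out[, in_edge := circuit$in_edge[old_next]]
  out[, in_kind := circuit$in_kind[old_next]]
  out[, step := seq_len(m)]
  out[]
}

#' Decompose the Eulerian circuit into local strains
#'
#' Cuts the circuit at chain edges and dummy back-edges; each remaining walk
#' runs from a receptor's first segment `b_i` to its last segment `t_i`.
#' The circuit direction is normalised so that receptor segments are
#' traversed forward. `h_i` counts the donor-segment blocks of each strain.
#'
#' @param circuit from [eulerian_circuit()].
#' @param graph the balanced `strain_graph`.
#' @return list of strains; each is a list with `strain_id`, `receptor`,
#'   `walk` (data.table seg_id, orientation), `h`.
#' @export
decompose_strains <- function(circuit, graph) {
  if (!nrow(circuit)) return(list())
  segs <- graph$segments
  b_ids <- graph$receptors$b_seg
  # normalise direction: b segments must be entered forward
  fwd_ok <- circuit[seg_id %in% b_ids & orientation == "+", .N]
  if (!fwd_ok) circuit <- .reverse_circuit(circuit)
  cuts <- which(circuit$in_kind %in% c("chain", "dummy"))
  if (!length(cuts)) {
    walks <- list(circuit)
  } else {
    # rotate so the circuit starts right after a cut
    m <- nrow(circuit)
    first <- cuts[1]
    rot <- c(first:m, seq_len(first - 1L))
    circuit <- circuit[rot][, step := .I]
    cuts <- which(circuit$in_kind %in% c("chain", "dummy"))
    bounds <- c(cuts, m + 1L)
    walks <- lapply(seq_along(cuts), function(i)
      circuit[bounds[i]:(bounds[i + 1L] - 1L)])
  }
  strains <- list()
  for (w in walks) {
    ok_walk <- function(x) {
      f <- segs[seg_id == x$seg_id[1]]
      l <- segs[seg_id == x$seg_id[nrow(x)]]
      nrow(f) == 1L && nrow(l) == 1L && f$role == "receptor_first" &&
        l$role == "receptor_last" && f$ref == l$ref &&
        x$orientation[1] == "+" && x$orientation[nrow(x)] == "+"
    }
    if (!ok_walk(w)) {
      # a walk traced in reverse reads t -> b backwards; flip it
      rev_w <- w[rev(seq_len(nrow(w)))]
      rev_w[, orientation := ifelse(orientation == "+", "-", "+")]
      if (ok_walk(rev_w)) w <- rev_w
      else warnf("decompose_strains: walk does not run b -> t on one receptor (kept as partial strain)")
    }
    first_seg <- segs[seg_id == w$seg_id[1]]
    rec <- first_seg$ref
    roles <- segs$role[match(w$seg_id, segs$seg_id)]
    donor_blocks <- rle(roles == "donor")
    h <- sum(donor_blocks$values)
    n_prev <- sum(vapply(strains, function(s) s$receptor == rec, logical(1)))
    strains[[length(strains) + 1L]] <- list(
      strain_id = sprintf("%s_strain_%d", rec, n_prev + 1L),
      receptor = rec,
      walk = w[, .(seg_id, orientation)],
      h = h)
  }
  strains
}

#' Emit reconstructed strain sequences and structure table
#'
#' @param strains from [decompose_strains()].
#' @param graph the balanced `strain_graph`.
#' @param genomes reference `DNAStringSet`.
#' @return list with `sequences` (`DNAStringSet`) and `structure`
#'   (`data.table`: strain_id, rank, source_ref, start, end, orientation,
#'   role).
#' @export
emit_sequences <- function(strains, graph, genomes) {
  segs <- graph$segments
  rows <- list(); seqs <- character(0)
  for (s in strains) {
    w <- copy(s$walk)[, rank := .I]
    si <- match(w$seg_id, segs$seg_id)
    w[, `:=`(ref = segs$ref[si], start = segs$start[si], end = segs$end[si],
             role = segs$role[si])]
    if (any(w$end > Biostrings::width(genomes)[match(w$ref, names(genomes))]))
      stopf("segment outside reference bounds for strain %s", s$strain_id)
    pieces <- vapply(seq_len(nrow(w)), function(i) {
      x <- as.character(Biostrings::subseq(genomes[[w$ref[i]]],
                                           start = w$start[i] + 1L, end = w$end[i]))
      if (w$orientation[i] == "-") revcomp_chr(x) else x
    }, character(1))
    seqs[s$strain_id] <- paste(pieces, collapse = "")
    rows[[length(rows) + 1L]] <- w[, .(strain_id = s$strain_id, rank,
                                       source_ref = ref, start, end,
                                       orientation, role)]
  }
  list(sequences = Biostrings::DNAStringSet(seqs),
       structure = if (length(rows)) rbindlist(rows) else data.table())
}

#' Reconstruct local strains from alignments and called breakpoints
#'
#' Orchestrates segmentation, copy-number estimation, graph construction,
#' dummy-edge insertion, connectivity repair, balancing, Eulerian traversal
#' and sequence emission.
#'
#' @param records alignment record table (or SAM/BAM path).
#' @param genomes reference `DNAStringSet`.
#' @param breakpoints table from [call_breakpoints()].
#' @param min_segment_cov,min_segment_len,receptors passed to
#'   [partition_references()].
#' @param copy_ub,node_cap passed to [balance_strain_graph()].
#' @param mapq_min used when `records` is a file path.
#' @return list with `graph`, `circuit`, `strains`, `sequences`,
#'   `structure`, `solver`.
#' @export
reconstruct_strains <- function(records, genomes, breakpoints,
                                min_segment_cov = 0.5, min_segment_len = 50L,
                                receptors = NULL, copy_ub = NULL,
                                node_cap = 2e6, mapq_min = 20L) {
  if (is.character(records)) records <- load_alignments(records, mapq_min)
  ref_lengths <- setNames(Biostrings::width(genomes), names(genomes))
  profile <- coverage_profile(records, ref_lengths)
  part <- partition_references(breakpoints, ref_lengths, profile,
                               min_segment_len = min_segment_len,
                               min_segment_cov = min_segment_cov,
                               receptors = receptors)
  if (!nrow(part$segments) || !nrow(part$receptors)) {
    return(list(graph = NULL, circuit = NULL, strains = list(),
                sequences = Biostrings::DNAStringSet(), structure = data.table(),
                solver = NULL))
  }
  part$segments <- estimate_copy_numbers(part$segments, profile)
  graph <- build_strain_graph(part, breakpoints)
  graph <- insert_dummy_edges(graph)
  graph <- repair_connectivity(graph)
  graph <- balance_strain_graph(graph, copy_ub = copy_ub, node_cap = node_cap)
  circuit <- eulerian_circuit(graph)
  strains <- decompose_strains(circuit, graph)
  emitted <- emit_sequences(strains, graph, genomes)
  list(graph = graph, circuit = circuit, strains = strains,
       sequences = emitted$sequences, structure = emitted$structure,
       solver = graph$solver)
}
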