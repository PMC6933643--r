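suppressPackageStartupMessages({
  library(data.table)
  library(Biostrings)
})

random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                    collapse = "")

# Build a coverage_profile directly from per-reference depth vectors.
make_profile <- function(depths) {
  cov <- lapply(depths, S4Vectors::Rle)
  structure(list(cov = cov,
                 mean_cov = vapply(cov, function(x) mean(as.numeric(x)), numeric(1)),
                 ref_lengths = vapply(depths, length, integer(1))),
            class = "coverage_profile")
}

# One-event fixture shared across tests (built once per test run).
.fixture_env <- new.env()
small_fixture <- function(seed = 7L, depth = 30, segments = 1L, error_rate = 0,
                          read_length = 100L) {
  key <- paste(seed, depth, segments, error_rate, read_length, sep = "_")
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  cfg <- sim_config(n_species = 3L, genome_length_range = c(40000L, 45000L),
                    n_events = 1L, segments_per_event = segments,
                    segment_length = 5000L, depth = depth,
                    read_length = read_length, error_rate = error_rate,
                    seed = seed, include_background = FALSE)
  genomes <- generate_reference_set(cfg)
  planted <- plant_hgt_events(genomes, cfg)
  readset <- simulate_reads(planted$strain_seqs, cfg, with_seq = TRUE)
  records <- suppressMessages(
    emit_truth_alignments(readset, planted$truth_segments, genomes,
                          as_table = TRUE))
  fx <- list(cfg = cfg, genomes = genomes, planted = planted,
             readset = readset, records = records)
  .fixture_env[[key]] <- fx
  fx
}

# Union-find connected components of the eps-graph (DBSCAN min_sample = 1
# oracle).
cc_oracle <- function(x, y, eps) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && (x[i] - x[j])^2 + (y[i] - y[j])^2 <= eps^2) {
      a <- find(i); b <- find(j)
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Exhaustive local alignment over tokens with match 1 / mismatch -1 / gap 0:
# equals the best-scoring pair of equal-length ordered subsequences.
brute_sw <- function(a, b, match = 1, mismatch = -1) {
  la <- length(a); lb <- length(b)
  if (la == 0 || lb == 0) return(0)
  subs <- function(v) {
    n <- length(v)
    out <- list(integer(0))
    for (m in seq_len(2^n - 1)) {
      out[[m + 1L]] <- which(bitwAnd(m, bitwShiftL(1L, seq_len(n) - 1L)) > 0L)
    }
    out
  }
  sa <- subs(seq_len(la)); sb <- subs(seq_len(lb))
  best <- 0
  for (ia in sa) for (ib in sb) {
    if (length(ia) != length(ib) || !length(ia)) next
    sc <- sum(ifelse(a[ia] == b[ib], match, mismatch))
    if (sc > best) best <- sc
  }
  best
}

# Brute-force optimum of the balance program by full enumeration of edge
# copies (chunked); same feasibility rules as the solver.
brute_balance <- function(lb_e, ub_e, t_e, vlb, t_v, ep1, ep2, s1, s2) {
  n_e <- length(lb_e); n_v <- length(vlb)
  grids <- lapply(seq_len(n_e), function(e) lb_e[e]:ub_e[e])
  combos <- as.matrix(do.call(expand.grid, grids))
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    x <- combos[r, ]
    m <- matrix(0L, n_v, 2)
    for (e in seq_len(n_e)) {
      m[ep1[e], s1[e]] <- m[ep1[e], s1[e]] + x[e]
      m[ep2[e], s2[e]] <- m[ep2[e], s2[e]] + x[e]
    }
    if (any(m[, 1] != m[, 2]) || any(m[, 1] < vlb)) next
    cost <- sum(abs(x - t_e)) + sum(abs(m[, 1] - t_v))
    if (cost < best) best <- cost
  }
  best
}

# Random bidirected balance instance within the property-test bounds.
random_balance_instance <- function(n_v_max = 6L, n_e_max = 10L, ub = 4L) {
  n_v <- sample(2:n_v_max, 1L)
  n_e <- sample(2:n_e_max, 1L)
  list(lb_e = sample(0:1, n_e, replace = TRUE),
       ub_e = rep(ub, n_e),
       t_e = sample(1:ub, n_e, replace = TRUE),
       vlb = rep(0L, n_v),
       t_v = sample(1:ub, n_v, replace = TRUE),
       ep1 = sample(n_v, n_e, replace = TRUE),
       ep2 = sample(n_v, n_e, replace = TRUE),
       s1 = sample(1:2, n_e, replace = TRUE),
       s2 = sample(1:2, n_e, replace = TRUE))
}

# Random balanced strain_graph built by superposing b->...->t walks plus the
# closing chain edge, so an Eulerian circuit must exist.
random_balanced_graph <- function(n_mid = 4L, n_walks = 3L) {
  n_seg <- n_mid + 2L
  segs <- data.table(seg_id = seq_len(n_seg),
                     ref = c("rec", rep("don", n_mid), "rec"),
                     start = c(0L, seq_len(n_mid) * 1000L, (n_mid + 1L) * 1000L),
                     end = c(1000L, seq_len(n_mid) * 1000L + 1000L, (n_mid + 2L) * 1000L),
                     role = c("receptor_first", rep("donor", n_mid), "receptor_last"),
                     cov = 1, copy_est = 1, target = 1L, copy = 0L)
  b <- 1L; t <- n_seg
  edge_tab <- new.env(); edge_tab$d <- list()
  add_edge <- function(s1, e1, s2, e2, kind) {
    key <- paste(s1, e1, s2, e2, kind)
    cur <- edge_tab$d[[key]]
    if (is.null(cur)) edge_tab$d[[key]] <- list(s1, e1, s2, e2, kind, 1L)
    else { cur[[6]] <- cur[[6]] + 1L; edge_tab$d[[key]] <- cur }
  }
  # each donor segment carries one fixed insertion orientation
  mid_orient <- setNames(sample(c("+", "-"), n_mid, replace = TRUE),
                         2:(n_seg - 1L))
  for (w in seq_len(n_walks)) {
    path <- c(b, sample(2:(n_seg - 1L), sample(0:n_mid, 1L)), t)
    orient <- c("+", unname(mid_orient[as.character(path[-c(1, length(path))])]), "+")
    for (i in seq_len(length(path) - 1L)) {
      e1 <- if (orient[i] == "+") "r" else "l"
      e2 <- if (orient[i + 1L] == "+") "l" else "r"
      add_edge(path[i], e1, path[i + 1L], e2, "observed")
    }
    add_edge(t, "r", b, "l", if (w == 1L) "chain" else "dummy")
  }
  el <- rbindlist(lapply(edge_tab$d, function(x)
    data.table(seg1 = x[[1]], end1 = x[[2]], seg2 = x[[3]], end2 = x[[4]],
               kind = x[[5]], support = 1L, target = x[[6]], copy = x[[6]],
               lb = 0L)))
  el[, edge_id := .I]
  setcolorder(el, c("edge_id", "seg1", "end1", "seg2", "end2", "kind",
                    "support", "target", "copy", "lb"))
  # vertex copies = attached copy sums (graph is balanced by construction)
  for (i in seq_len(n_seg)) {
    cl <- sum(el[seg1 == i & end1 == "l", copy]) + sum(el[seg2 == i & end2 == "l", copy])
    segs$copy[i] <- cl
  }
  segs[, target := pmax(1L, copy)]
  segs <- segs[copy > 0L]
  structure(list(segments = segs, edges = el,
                 receptors = data.table(i = 1L, ref = "rec", b_seg = b, t_seg = t)),
            class = "strain_graph")
}
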