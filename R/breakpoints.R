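#' DBSCAN clustering of 2-D junction coordinates
#'
#' Density-based clustering with Euclidean distance, as used to group the
#' junction-pair points of one reference pair. With `min_sample = 1` (the
#' method's default) every point is a core point and the result is exactly
#' the connected components of the graph linking points at distance
#' `<= eps`; with larger `min_sample` border/noise handling follows the
#' classic algorithm (noise labelled 0).
#'
#' Clusters are numbered deterministically by their minimal point (ordered
#' by `x`, then `y`).
#'
#' @param x,y numeric coordinates.
#' @param eps neighbourhood radius (> 0).
#' @param min_sample minimum neighbourhood size of a core point (>= 1; a
#'   point counts itself).
#' @return integer cluster labels (0 = noise, only possible when
#'   `min_sample > 1`).
#' @export
dbscan_cluster <- function(x, y, eps, min_sample = 1L) {
  stopifnot(length(x) == length(y))
  if (eps <= 0) stopf("eps must be > 0")
  if (min_sample < 1) stopf("min_sample must be >= 1")
  n <- length(x)
  if (n == 0L) return(integer(0))
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  nb <- d2 <= eps^2
  core <- rowSums(nb) >= min_sample
  labels <- integer(n)  # 0 = unvisited/noise
  cl <- 0L
  for (i in order(x, y)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    frontier <- i
    labels[i] <- cl
    while (length(frontier)) {
      nxt <- integer(0)
      for (p in frontier) {
        if (!core[p]) next
        reach <- which(nb[p, ] & labels == 0L)
        labels[reach] <- cl
        nxt <- c(nxt, reach)
      }
      frontier <- unique(nxt)
    }
  }
  labels
}

#' Alignment quality of a split-read part
#'
#' `q_s = m / l`, the fraction of matched bases of the partner-side part of
#' a split read; `m` must be at least 15 (shorter matches are discarded at
#' extraction). Perfect parts (`q_s = 1`) are clamped to `1 - 1/(2l)` so the
#' downstream `log(1 - q_s)` stays finite while preserving the ordering at
#' the part's own resolution.
#'
#' @param m matched bases (integer, >= 15 after upstream filtering).
#' @param l part length (> 0).
#' @return quality in (0, 1).
#' @export
split_quality <- function(m, l) {
  if (any(l <= 0)) stopf("invalid split: part length must be > 0")
  q <- m / l
  if (any(q <= 0 | q > 1)) stopf("invalid split: m must be in (0, l]")
  pmin(q, 1 - 1 / (2 * l))
}

#' Quality score of a candidate breakpoint position
#'
#' `score = 1 - sum_s log(1 - q_s)` over the supporting split-read
#' qualities (natural log). The empty sum gives 1; each added support with
#' `q_s` in (0,1) strictly increases the score.
#'
#' @param qs vector of split qualities in (0, 1).
#' @return the score (>= 1).
#' @export
position_score <- function(qs) {
  if (length(qs) && any(qs <= 0 | qs >= 1))
    stopf("internal error: split quality outside (0, 1) after clamping")
  1 - sum(log(1 - qs))
}

# Score all candidate position pairs of one cluster and pick the best.
# splits: data.table with coord_a/coord_b, m_a/l_a, m_b/l_b, dir_a/dir_b.
.call_from_splits <- function(splits) {
  cand <- unique(splits[, .(coord_a, coord_b)])
  best <- NULL
  setorder(cand, coord_a, coord_b)
  for (i in seq_len(nrow(cand))) {
    p1 <- cand$coord_a[i]; p2 <- cand$coord_b[i]
    s_at_p1 <- splits[coord_a == p1]
    s_at_p2 <- splits[coord_b == p2]
    score_p2 <- position_score(split_quality(s_at_p1$m_b, s_at_p1$l_b))
    score_p1 <- position_score(split_quality(s_at_p2$m_a, s_at_p2$l_a))
    sc <- score_p1 + score_p2
    if (is.null(best) || sc > best$score + 1e-12) {
      sup <- splits[coord_a == p1 & coord_b == p2]
      best <- list(p1 = p1, p2 = p2, score = sc,
                   dir1 = names(sort(table(sup$dir_a), decreasing = TRUE))[1],
                   dir2 = names(sort(table(sup$dir_b), decreasing = TRUE))[1])
    }
  }
  best
}

#' Call breakpoint pairs from junction-pair clusters and split reads
#'
#' For each canonical reference pair, junction pairs are clustered with
#' DBSCAN (`eps` = average insert size, `min_sample = 1`); split reads whose
#' coordinate point lies within `eps` of a cluster member are attached;
#' candidate position pairs are the distinct split coordinates, scored with
#' [position_score()] on each side, and the highest combined score (sum of
#' the two sides; ties broken by smallest `(p1, p2)`) is reported as the
#' cluster's breakpoint pair. Clusters with junction support but no split
#' support are reported as imprecise (cluster medoid, `precise = FALSE`).
#'
#' @param junctions from [extract_junction_pairs()].
#' @param splits from [extract_split_reads()].
#' @param eps clustering radius; the average insert size.
#' @param min_sample DBSCAN minimum neighbourhood size (default 1).
#' @return `data.table`: ref1, pos1, dir1, ref2, pos2, dir2, score,
#'   n_junction, n_split, precise; `ref1 < ref2` (canonical order).
#' @export
call_breakpoints <- function(junctions, splits, eps, min_sample = 1L) {
  empty <- data.table(ref1 = character(0), pos1 = integer(0), dir1 = character(0),
                      ref2 = character(0), pos2 = integer(0), dir2 = character(0),
                      score = numeric(0), n_junction = integer(0),
                      n_split = integer(0), precise = logical(0))
  if (!nrow(junctions)) return(empty)
  out <- list()
  for (rp in split(junctions, by = c("ref_x", "ref_y"), sorted = TRUE)) {
    rx <- rp$ref_x[1]; ry <- rp$ref_y[1]
    labels <- dbscan_cluster(rp$pos_x, rp$pos_y, eps, min_sample)
    sp <- splits[ref_a == rx & ref_b == ry]
    for (cl in sort(unique(labels[labels > 0L]))) {
      mem <- rp[labels == cl]
      attach_idx <- integer(0)
      if (nrow(sp)) {
        d2min <- vapply(seq_len(nrow(sp)), function(i) {
          min((sp$coord_a[i] - mem$pos_x)^2 + (sp$coord_b[i] - mem$pos_y)^2)
        }, numeric(1))
        attach_idx <- which(d2min <= eps^2)
      }
      if (length(attach_idx)) {
        best <- .call_from_splits(sp[attach_idx])
        out[[length(out) + 1L]] <- data.table(
          ref1 = rx, pos1 = best$p1, dir1 = best$dir1,
          ref2 = ry, pos2 = best$p2, dir2 = best$dir2,
          score = best$score, n_junction = nrow(mem),
          n_split = length(attach_idx), precise = TRUE)
      } else {
        out[[length(out) + 1L]] <- data.table(
          ref1 = rx, pos1 = as.integer(round(median(mem$pos_x))), dir1 = NA_character_,
          ref2 = ry, pos2 = as.integer(round(median(mem$pos_y))), dir2 = NA_character_,
          score = NA_real_, n_junction = nrow(mem), n_split = 0L,
          precise = FALSE)
      }
    }
  }
  res <- rbindlist(out)
  setorder(res, ref1, ref2, pos1, pos2)
  res[]
}

#' Detect HGT breakpoints from an alignment file or record table
#'
#' End-to-end breakpoint detection: load/filter alignments, extract junction
#' pairs and split reads, estimate the average insert size (unless `eps` is
#' given) and call breakpoint pairs per reference pair.
#'
#' @param alignments path to SAM/BAM, or a record table.
#' @param eps DBSCAN radius; `NULL` = estimate the average insert size from
#'   concordant pairs ([estimate_insert_size()]).
#' @param min_sample DBSCAN minimum neighbourhood size.
#' @param min_match minimum matched bases of a split part.
#' @param mapq_min minimum mapping quality (file input only).
#' @return as [call_breakpoints()].
#' @export
detect_breakpoints <- function(alignments, eps = NULL, min_sample = 1L,
                               min_match = 15L, mapq_min = 20L) {
  records <- if (is.character(alignments)) load_alignments(alignments, mapq_min)
             else alignments
  junctions <- extract_junction_pairs(records)
  splits <- extract_split_reads(records, min_match = min_match)
  if (is.null(eps)) eps <- estimate_insert_size(records)$mean
  call_breakpoints(junctions, splits, eps = eps, min_sample = min_sample)
}
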