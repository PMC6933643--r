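.bp_row <- function(ref1, pos1, dir1, ref2, pos2, dir2) {
  data.table::data.table(ref1 = ref1, pos1 = as.integer(pos1), dir1 = dir1,
                         ref2 = ref2, pos2 = as.integer(pos2), dir2 = dir2,
                         score = 10, n_junction = 5L, n_split = 3L,
                         precise = TRUE)
}

# calls of one forward insertion: donor[2000,12000) into receptor at 4000
.single_insertion_calls <- function() {
  rbind(.bp_row("don", 2000L, "R", "rec", 4000L, "L"),
        .bp_row("don", 12000L, "L", "rec", 4000L, "R"))
}

.single_insertion_profile <- function(rec_len = 10000L, don_len = 20000L,
                                      background = TRUE) {
  don <- rep(if (background) 30 else 0, don_len)
  don[2001:12000] <- don[2001:12000] + 30
  make_profile(list(rec = rep(30, rec_len), don = don))
}

test_that("references are cut at breakpoints into tiling segments", {
  prof <- .single_insertion_profile()
  part <- partition_references(.single_insertion_calls(),
                               c(rec = 10000L, don = 20000L), prof)
  segs <- part$segments
  rec_segs <- segs[segs$ref == "rec", ]
  expect_equal(rec_segs$start, c(0L, 4000L))
  expect_equal(rec_segs$end, c(4000L, 10000L))
  don_segs <- segs[segs$ref == "don", ]
  expect_equal(don_segs$start, c(0L, 2000L, 12000L))
  expect_equal(don_segs$end, c(2000L, 12000L, 20000L))
  # tiling invariant: boundaries are the cuts plus the reference ends
  expect_equal(sort(unique(c(don_segs$start, don_segs$end))),
               c(0L, 2000L, 12000L, 20000L))
  expect_equal(part$receptors$ref, "rec")
  expect_equal(rec_segs$role, c("receptor_first", "receptor_last"))
  # no breakpoints -> nothing emitted
  empty <- partition_references(.single_insertion_calls()[0],
                                c(rec = 10000L), prof)
  expect_equal(nrow(empty$segments), 0L)
  # breakpoint on unknown reference -> error naming it
  bad <- .bp_row("ghost", 10L, "L", "rec", 4000L, "R")
  expect_error(partition_references(bad, c(rec = 10000L, don = 20000L), prof),
               "ghost")
})

test_that("uncovered donor flanks are dropped under strain-only coverage", {
  prof <- .single_insertion_profile(background = FALSE)
  part <- partition_references(.single_insertion_calls(),
                               c(rec = 10000L, don = 20000L), prof)
  don_segs <- part$segments[part$segments$ref == "don", ]
  expect_equal(nrow(don_segs), 1L)
  expect_equal(c(don_segs$start, don_segs$end), c(2000L, 12000L))
})

test_that("copy numbers are coverage ratios against the retained reference mean", {
  segs <- data.table::data.table(
    seg_id = 1:3, ref = c("r", "r", "r"), start = c(0L, 1000L, 4000L),
    end = c(1000L, 4000L, 10000L), role = "receptor_internal",
    cov = c(60, 20, 20))
  # length-weighted mean = (60*1000 + 20*3000 + 20*6000) / 10000 = 24
  est <- estimate_copy_numbers(segs)
  expect_equal(est$copy_est, c(60, 20, 20) / 24)
  expect_equal(est$target, c(2L, 1L, 1L))
  # equal coverage -> copy 1
  segs2 <- data.table::data.table(seg_id = 1L, ref = "r", start = 0L,
                                  end = 100L, role = "donor", cov = 20)
  expect_equal(estimate_copy_numbers(segs2)$copy_est, 1.0)
  # a donor segment inserted once into an equally deep receptor doubles up
  prof <- .single_insertion_profile(background = TRUE)
  part <- partition_references(.single_insertion_calls(),
                               c(rec = 10000L, don = 20000L), prof)
  est3 <- estimate_copy_numbers(part$segments, prof)
  don_mid <- est3[est3$ref == "don" & est3$start == 2000L, ]
  expect_equal(don_mid$copy_est, 60 / ((30 * 10000 + 60 * 10000) / 20000),
               tolerance = 0.01)
})

test_that("graph construction wires the single-insertion anatomy", {
  prof <- .single_insertion_profile(background = FALSE)
  part <- partition_references(.single_insertion_calls(),
                               c(rec = 10000L, don = 20000L), prof)
  part$segments <- estimate_copy_numbers(part$segments, prof)
  g <- build_strain_graph(part, .single_insertion_calls())
  expect_s3_class(g, "strain_graph")
  obs <- g$edges[g$edges$kind == "observed", ]
  expect_equal(nrow(obs), 2L)
  adj <- g$edges[g$edges$kind == "adjacency", ]
  expect_equal(nrow(adj), 1L)   # rec b -> rec t (the cut receptor adjacency)
  expect_equal(adj$lb, 0L)
  # reverse-oriented insertion attaches the donor through opposite ends
  calls_rev <- rbind(.bp_row("don", 12000L, "L", "rec", 4000L, "L"),
                     .bp_row("don", 2000L, "R", "rec", 4000L, "R"))
  g2 <- build_strain_graph(part, calls_rev)
  obs2 <- g2$edges[g2$edges$kind == "observed", ]
  don_seg <- g2$segments[g2$segments$ref == "don", seg_id]
  ends_on_don <- c(obs2[obs2$seg1 == don_seg, end1], obs2[obs2$seg2 == don_seg, end2])
  # both junctions exist and use both donor ends
  expect_setequal(ends_on_don, c("l", "r"))
  # no breakpoints -> empty graph
  g3 <- build_strain_graph(list(segments = part$segments[0],
                                receptors = part$receptors[0]),
                           .single_insertion_calls()[0])
  expect_equal(nrow(g3$edges), 0L)
})

test_that("dummy and chain edges follow the copy-number recipe", {
  mk_graph <- function(cb) {
    segs <- data.table::data.table(
      seg_id = 1:2, ref = "rec", start = c(0L, 5000L), end = c(5000L, 10000L),
      role = c("receptor_first", "receptor_last"), cov = 30,
      copy_est = as.numeric(cb), target = as.integer(cb), copy = NA_integer_)
    edges <- data.table::data.table(
      edge_id = integer(0), seg1 = integer(0), end1 = character(0),
      seg2 = integer(0), end2 = character(0), kind = character(0),
      support = integer(0), target = integer(0), copy = integer(0),
      lb = integer(0))
    structure(list(segments = segs, edges = edges,
                   receptors = data.table::data.table(i = 1L, ref = "rec",
                                                      b_seg = 1L, t_seg = 2L)),
              class = "strain_graph")
  }
  g3 <- insert_dummy_edges(mk_graph(3L))
  dummy <- g3$edges[g3$edges$kind == "dummy", ]
  expect_equal(dummy$copy, 2L)               # c(b) - 1
  expect_equal(c(dummy$seg1, dummy$seg2), c(2L, 1L))
  expect_equal(c(dummy$end1, dummy$end2), c("r", "l"))
  g1 <- insert_dummy_edges(mk_graph(1L))
  expect_equal(nrow(g1$edges[g1$edges$kind == "dummy", ]), 0L)  # omitted at 0
  expect_equal(nrow(g1$edges[g1$edges$kind == "chain", ]), 1L)  # t_1 -> b_1
  # k = 3 receptors: chain edges close the cycle t_i -> b_{i+1}, t_3 -> b_1
  segs <- data.table::data.table(
    seg_id = 1:6, ref = rep(c("r1", "r2", "r3"), each = 2),
    start = rep(c(0L, 5000L), 3), end = rep(c(5000L, 10000L), 3),
    role = rep(c("receptor_first", "receptor_last"), 3), cov = 30,
    copy_est = 1, target = 1L, copy = NA_integer_)
  gk <- structure(list(
    segments = segs,
    edges = mk_graph(1L)$edges,
    receptors = data.table::data.table(i = 1:3, ref = c("r1", "r2", "r3"),
                                       b_seg = c(1L, 3L, 5L),
                                       t_seg = c(2L, 4L, 6L))),
    class = "strain_graph")
  gk <- insert_dummy_edges(gk)
  ch <- gk$edges[gk$edges$kind == "chain", ]
  expect_equal(nrow(ch), 3L)
  expect_equal(ch$copy, rep(1L, 3))
  expect_setequal(paste(ch$seg1, ch$seg2), c("2 3", "4 5", "6 1"))
})

test_that("connectivity repair removes orphans, patches free ends, and is idempotent", {
  fx <- small_fixture()
  bps <- suppressMessages(detect_breakpoints(fx$records))
  lens <- setNames(width(fx$genomes), names(fx$genomes))
  prof <- coverage_profile(fx$records, lens)
  part <- partition_references(bps, lens, prof)
  part$segments <- estimate_copy_numbers(part$segments, prof)
  g <- insert_dummy_edges(build_strain_graph(part, bps))
  r1 <- suppressMessages(repair_connectivity(g))
  r2 <- suppressMessages(repair_connectivity(r1))
  expect_equal(r1$edges, r2$edges)
  expect_equal(r1$segments, r2$segments)
  # an isolated segment unreachable from any receptor is removed
  iso <- data.table::copy(g)
  iso$segments <- rbind(iso$segments,
                        data.table::data.table(seg_id = 99L, ref = "ref_999",
                                               start = 0L, end = 1000L,
                                               role = "donor", cov = 1,
                                               copy_est = 1, target = 1L,
                                               copy = NA_integer_))
  class(iso) <- "strain_graph"
  r3 <- suppressMessages(repair_connectivity(iso))
  expect_false(99L %in% r3$segments$seg_id)
})
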