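test_that("exact balancing matches brute-force enumeration on random instances", {
  set.seed(31)
  for (rep in 1:12) {
    inst <- random_balance_instance()
    got <- hgtrecon:::.balance_search(inst$lb_e, inst$ub_e, inst$t_e, inst$vlb,
                                      inst$t_v, inst$ep1, inst$ep2, inst$s1,
                                      inst$s2)
    want <- brute_balance(inst$lb_e, inst$ub_e, inst$t_e, inst$vlb, inst$t_v,
                          inst$ep1, inst$ep2, inst$s1, inst$s2)
    expect_true(got$exact)
    expect_equal(got$cost, want)
  }
})

test_that("balancing resolves the path and star textbook cases", {
  # cycle a -> u -> b -> a, edge targets 1, t(u) = 2: cheaper to keep
  # c(u) = 1 (cost 1) than to raise the whole cycle (cost >= 2)
  got <- hgtrecon:::.balance_search(
    lb_e = c(1L, 1L, 1L), ub_e = c(4L, 4L, 4L), t_e = c(1L, 1L, 1L),
    vlb = c(0L, 0L, 0L), t_v = c(1L, 2L, 1L),
    ep1 = c(1L, 2L, 3L), ep2 = c(2L, 3L, 1L),
    s1 = c(2L, 2L, 2L), s2 = c(1L, 1L, 1L))
  expect_equal(got$cost, 1)
  expect_equal(got$cv[2], 1L)
  # star: in-edges {1,1} to u, one out-edge, t(u)=2 -> raise the out edge
  # x ->(e1) u, y ->(e2) u, u ->(e3) z, z ->(e4) x, z ->(e5) y
  got2 <- hgtrecon:::.balance_search(
    lb_e = rep(1L, 5), ub_e = rep(4L, 5), t_e = c(1L, 1L, 1L, 1L, 1L),
    vlb = rep(0L, 4), t_v = c(1L, 2L, 1L, 2L),
    ep1 = c(1L, 3L, 2L, 4L, 4L), ep2 = c(2L, 2L, 4L, 1L, 3L),
    s1 = c(2L, 2L, 2L, 2L, 2L), s2 = c(1L, 1L, 1L, 1L, 1L))
  expect_equal(got2$cost, 1)
  expect_equal(got2$cv[2], 2L)
  expect_equal(got2$val[3], 2L)
})

test_that("an already balanced graph keeps its copies with objective 0", {
  set.seed(5)
  g <- random_balanced_graph()
  before <- data.table::copy(g$edges$copy)
  bal <- balance_strain_graph(g)
  expect_equal(bal$solver$objective, 0)
  expect_equal(bal$edges$copy, before[before > 0])
  expect_true(verify_balance(bal)$balanced)
})

test_that("verify_balance flags violations", {
  g <- random_balanced_graph()
  expect_true(verify_balance(g)$balanced)
  g$segments$copy[1] <- g$segments$copy[1] + 1L
  vb <- verify_balance(g)
  expect_false(vb$balanced)
  expect_equal(nrow(vb$violations), 1L)
  empty <- structure(list(segments = g$segments[0], edges = g$edges[0],
                          receptors = g$receptors[0]), class = "strain_graph")
  expect_true(verify_balance(empty)$balanced)
})

test_that("the Eulerian circuit traverses every edge exactly copy times", {
  set.seed(17)
  for (rep in 1:8) {
    g <- random_balanced_graph(n_mid = sample(2:6, 1), n_walks = sample(1:4, 1))
    circ <- eulerian_circuit(g)
    got <- table(circ$in_edge)
    want <- setNames(g$edges$copy, g$edges$edge_id)
    want <- want[want > 0]
    expect_equal(length(got), length(want))
    expect_equal(as.integer(got[as.character(names(want))]), unname(want))
    # each segment visited exactly copy(u) times
    vis <- table(circ$seg_id)
    expect_equal(as.integer(vis[as.character(g$segments$seg_id)]),
                 g$segments$copy)
  }
})

test_that("circuit precondition failures are reported", {
  g <- random_balanced_graph()
  g$segments$copy[1] <- g$segments$copy[1] + 1L
  expect_error(eulerian_circuit(g), "not balanced")
})

test_that("decomposition cuts at chain/dummy edges and conserves the circuit", {
  set.seed(23)
  g <- random_balanced_graph(n_mid = 4, n_walks = 3)
  circ <- eulerian_circuit(g)
  strains <- decompose_strains(circ, g)
  n_cut <- sum(circ$in_kind %in% c("chain", "dummy"))
  expect_equal(length(strains), n_cut)
  # completeness: strain segments plus one cut edge per strain = circuit
  expect_equal(sum(vapply(strains, function(s) nrow(s$walk), integer(1))),
               nrow(circ))
  for (s in strains) {
    first <- g$segments[g$segments$seg_id == s$walk$seg_id[1], ]
    last <- g$segments[g$segments$seg_id == s$walk$seg_id[nrow(s$walk)], ]
    expect_equal(first$role, "receptor_first")
    expect_equal(last$role, "receptor_last")
    expect_equal(first$ref, last$ref)
    expect_equal(s$walk$orientation[1], "+")
  }
})

test_that("end-to-end round trip recovers the exact strain sequence", {
  fx <- small_fixture(depth = 30)
  res <- suppressMessages(run_hgt_pipeline(fx$records, fx$genomes))
  expect_equal(length(res$strains), 1L)
  expect_identical(as.character(res$sequences[[1]]),
                   as.character(fx$planted$strain_seqs[[1]]))
  # structure table mirrors the truth (3 segments, donor in the middle)
  st <- res$structure
  expect_equal(nrow(st), 3L)
  expect_equal(st$role, c("receptor_first", "donor", "receptor_last"))
  truth <- fx$planted$truth_segments
  expect_equal(st$start, truth$start)
  expect_equal(st$end, truth$end)
  expect_equal(st$orientation, truth$orientation)
})

test_that("noisy reads still recover segment order and orientation", {
  fx <- small_fixture(depth = 30, error_rate = 0.001, seed = 19L)
  res <- suppressMessages(run_hgt_pipeline(fx$records, fx$genomes))
  st <- res$structure
  truth <- fx$planted$truth_segments
  expect_equal(nrow(st), nrow(truth))
  expect_equal(st$source_ref, truth$source_ref)
  expect_equal(st$orientation, truth$orientation)
})

test_that("emitted sequences honour segment orientation", {
  genomes <- Biostrings::DNAStringSet(c(g1 = "ACGTACGTAA", g2 = "TTTTCCCCGG"))
  segs <- data.table::data.table(seg_id = 1:2, ref = c("g1", "g2"),
                                 start = c(0L, 2L), end = c(4L, 8L),
                                 role = c("receptor_first", "donor"),
                                 cov = 1, copy_est = 1, target = 1L, copy = 1L)
  g <- structure(list(segments = segs, edges = data.table::data.table(),
                      receptors = data.table::data.table(i = 1L, ref = "g1",
                                                         b_seg = 1L, t_seg = 1L)),
                 class = "strain_graph")
  strains <- list(list(strain_id = "s1", receptor = "g1",
                       walk = data.table::data.table(seg_id = 1:2,
                                                     orientation = c("+", "-")),
                       h = 1L))
  out <- emit_sequences(strains, g, genomes)
  expect_equal(as.character(out$sequences[[1]]),
               paste0("ACGT", as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString("TTCCCC")))))
})
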