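test_that("reference generation is deterministic and validates its config", {
  cfg <- sim_config(n_species = 4L, genome_length_range = c(1000L, 1000L),
                    n_events = 1L, seed = 3L)
  g1 <- generate_reference_set(cfg)
  g2 <- generate_reference_set(cfg)
  expect_length(g1, 4L)
  expect_true(all(width(g1) == 1000L))
  expect_identical(as.character(g1), as.character(g2))
  g3 <- generate_reference_set(sim_config(n_species = 4L, seed = 4L))
  expect_false(identical(as.character(g1), as.character(g3)))
  expect_error(generate_reference_set(sim_config(n_species = 1L)),
               "n_species")
  expect_error(sim_config(depth = 0), "depth")
  expect_error(sim_config(segment_length = 0), "segment_length")
  expect_warning(sim_config(insert_mean = 100, read_length = 100),
                 "insert_mean")
})

test_that("a single insertion yields the expected strain anatomy", {
  fx <- small_fixture()
  segs <- fx$planted$truth_segments
  expect_equal(nrow(segs), 3L)
  expect_equal(segs$role, c("receptor", "donor", "receptor"))
  expect_equal(segs$source_ref[1], segs$source_ref[3])
  # concatenated segment lengths equal the strain sequence length
  expect_equal(sum(segs$end - segs$start),
               width(fx$planted$strain_seqs)[[1]])
  # two junction breakpoint pairs for one transferred segment
  expect_equal(nrow(fx$planted$truth_breakpoints), 2L)
  # segment length honoured; default is the 10 kb protocol value
  expect_equal(segs[2, end - start], 5000L)
  expect_equal(sim_config()$segment_length, 10000L)
})

test_that("one event with two segments at distinct loci gives 5 segments and 4 junctions", {
  fx <- small_fixture(segments = 2L)
  segs <- fx$planted$truth_segments
  expect_equal(nrow(segs), 5L)
  expect_equal(sum(segs$role == "donor"), 2L)
  expect_equal(nrow(fx$planted$truth_breakpoints), 4L)
  # every strain begins and ends with receptor-derived segments
  for (sid in unique(segs$strain_id)) {
    s <- segs[segs$strain_id == sid, ]
    expect_equal(s$role[1], "receptor")
    expect_equal(s$role[nrow(s)], "receptor")
  }
})

test_that("read counts follow round(depth * length / (2 * read_length))", {
  seqs <- DNAStringSet(setNames(paste(rep("ACGT", 25000), collapse = ""), "x"))
  cfg <- sim_config(n_species = 2L, depth = 20, read_length = 100L, seed = 5L)
  rs <- simulate_reads(seqs, cfg, with_seq = FALSE)
  expect_equal(nrow(rs$reads), 2L * round(20 * 100000 / (2 * 100)))
  cfg2 <- sim_config(n_species = 2L, depth = 2, read_length = 100L, seed = 5L)
  cfg70 <- sim_config(n_species = 2L, depth = 70, read_length = 100L, seed = 5L)
  n2 <- nrow(simulate_reads(seqs, cfg2, with_seq = FALSE)$reads)
  n70 <- nrow(simulate_reads(seqs, cfg70, with_seq = FALSE)$reads)
  expect_equal(n70 / n2, 70 / 2, tolerance = 1e-3)
})

test_that("error-free reads substring-match their source", {
  fx <- small_fixture()
  rs <- fx$readset
  src_chr <- as.character(fx$planted$strain_seqs)
  idx <- sample(nrow(rs$reads), 50)
  for (i in idx) {
    r <- rs$reads[i]
    sub <- substr(src_chr[[r$src]], r$rs + 1L, r$re)
    found <- rs$sequences[i]
    if (r$mate == 2L) sub <- as.character(reverseComplement(DNAString(sub)))
    expect_identical(found, sub)
  }
})

test_that("base conservation: total simulated bases match the depth formula", {
  fx <- small_fixture()
  lens <- width(fx$planted$strain_seqs)
  expected <- sum(round(fx$cfg$depth * lens / (2 * fx$cfg$read_length))) *
    2 * fx$cfg$read_length
  expect_equal(nrow(fx$readset$reads) * fx$cfg$read_length, expected)
})

test_that("truth alignments encode concordant pairs, splits and junction pairs", {
  fx <- small_fixture()
  rec <- fx$records
  # concordant pair fully inside one receptor segment
  conc <- rec[supp == FALSE & rname == mrnm]
  expect_gt(nrow(conc), 0)
  # junction pairs exist (mates on two references across the insertion)
  expect_gt(nrow(rec[supp == FALSE & mrnm != "*" & rname != mrnm]), 0)
  # split records: supplementary + primary with reciprocal soft clips
  sup <- rec[supp == TRUE]
  expect_gt(nrow(sup), 0)
  prim <- rec[supp == FALSE]
  one <- merge(sup[1], prim, by = c("qname", "first"))
  expect_equal(one$rwidth.x + one$rwidth.y, fx$cfg$read_length)
})

test_that("split clip arithmetic matches a read crossing at offset 30", {
  # hand-built strain: receptor[0,1000) + donor[0,500) '+' + receptor[1000,2000)
  genomes <- DNAStringSet(c(rec = random_dna_str(2000), don = random_dna_str(500)))
  segs <- data.table::data.table(
    strain_id = "s", rank = 1:3, source_ref = c("rec", "don", "rec"),
    start = c(0L, 0L, 1000L), end = c(1000L, 500L, 2000L),
    orientation = "+", role = c("receptor", "donor", "receptor"))
  reads <- data.table::data.table(
    qname = "r1", src = "s", mate = 1L, rs = 930L, re = 1030L, strand = "+")
  rs <- structure(list(reads = reads,
                       err = data.table::data.table(read_row = integer(0),
                                                    offset = integer(0)),
                       sequences = NULL, read_length = 100L, with_seq = FALSE,
                       src_names = "s"), class = "hgt_readset")
  rec <- suppressMessages(
    emit_truth_alignments(rs, segs, genomes, min_align_len = 30L, as_table = TRUE))
  expect_equal(nrow(rec), 2L)
  p <- rec[supp == FALSE]; s <- rec[supp == TRUE]
  expect_equal(p$rname, "rec"); expect_equal(s$rname, "don")
  expect_equal(p$cigar, "70M30S")   # 70 bp on the receptor, 30 bp clipped
  expect_equal(s$cigar, "70S30M")
  expect_equal(p$pos, 930L); expect_equal(s$pos, 0L)
})

test_that("simulated data sets are byte-identical per seed", {
  cfg <- sim_config(n_species = 2L, genome_length_range = c(8000L, 9000L),
                    n_events = 1L, segment_length = 1000L, depth = 5,
                    seed = 42L, include_background = FALSE,
                    min_locus_gap = 500, end_margin = 500)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  suppressMessages(simulate_hgt_dataset(cfg, d1))
  suppressMessages(simulate_hgt_dataset(cfg, d2))
  for (f in c("references.fasta", "strains.fasta", "reads_1.fastq",
              "truth.sam", "truth_breakpoints.tsv", "truth_strains.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})
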