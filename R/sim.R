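#' Simulation configuration for synthetic HGT benchmarks
#'
#' Bundles every knob of the built-in benchmark generator: synthetic reference
#' genomes, planted HGT events (transferred donor segments copied into a
#' receptor), and WGSIM-like paired-end read simulation. Identical
#' configurations (including `seed`) reproduce byte-identical outputs.
#'
#' @param n_species number of synthetic reference genomes (>= 2; one event
#'   needs at least a receptor and a donor).
#' @param genome_length_range two integers; genome lengths are drawn uniformly
#'   from this range (bp).
#' @param n_events number of HGT events to plant.
#' @param segments_per_event transferred segments per event (the benchmark
#'   protocol varies this from 1 to 5).
#' @param segment_length length of each transferred segment in bp (default
#'   10000, the 10 kb segments of the benchmark protocol).
#' @param depth fold coverage of the paired-end read simulation.
#' @param read_length read length in bp.
#' @param insert_mean,insert_sd fragment (outer insert) size Normal
#'   parameters in bp.
#' @param error_rate per-base substitution probability.
#' @param seed integer seed; all stages derive their RNG streams from it.
#' @param shared_locus if `TRUE`, all segments of one event are chained at a
#'   single receptor locus; otherwise each segment gets its own locus.
#' @param single_receptor if `TRUE`, all events target the same receptor
#'   genome (the complicated-event benchmark layout); otherwise each event
#'   draws its receptor at random.
#' @param include_background if `TRUE`, the original (uninserted) reference
#'   genomes also contribute reads in addition to the local strains.
#' @param min_locus_gap minimum distance between insertion loci on one
#'   receptor (default `2 * insert_mean`), keeping junction clusters distinct.
#' @param end_margin insertion positions keep this distance from the receptor
#'   ends (default `insert_mean`); positions are always strictly inside.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_species = 5L,
                       genome_length_range = c(150000L, 250000L),
                       n_events = 2L,
                       segments_per_event = 1L,
                       segment_length = 10000L,
                       depth = 30,
                       read_length = 100L,
                       insert_mean = 500,
                       insert_sd = 50,
                       error_rate = 0.001,
                       seed = 1L,
                       shared_locus = FALSE,
                       single_receptor = FALSE,
                       include_background = TRUE,
                       min_locus_gap = NULL,
                       end_margin = NULL) {
  if (length(genome_length_range) != 2 || any(genome_length_range < 1) ||
      genome_length_range[1] > genome_length_range[2])
    stopf("invalid config: genome_length_range must be an increasing pair of positive lengths")
  if (segment_length < 1) stopf("invalid config: segment_length must be >= 1")
  if (segments_per_event < 1) stopf("invalid config: segments_per_event must be >= 1")
  if (segments_per_event > 5)
    warnf("segments_per_event > 5 is outside the benchmark protocol range [1, 5]")
  if (depth <= 0) stopf("invalid config: depth must be > 0")
  if (read_length < 1) stopf("invalid config: read_length must be >= 1")
  if (error_rate < 0 || error_rate > 1) stopf("invalid config: error_rate must be in [0, 1]")
  if (insert_mean < 2 * read_length)
    warnf("insert_mean < 2 * read_length: mates will overlap; allowed but unusual")
  cfg <- list(
    n_species = as.integer(n_species),
    genome_length_range = as.integer(genome_length_range),
    n_events = as.integer(n_events),
    segments_per_event = as.integer(segments_per_event),
    segment_length = as.integer(segment_length),
    depth = as.numeric(depth),
    read_length = as.integer(read_length),
    insert_mean = as.numeric(insert_mean),
    insert_sd = as.numeric(insert_sd),
    error_rate = as.numeric(error_rate),
    seed = as.integer(seed),
    shared_locus = isTRUE(shared_locus),
    single_receptor = isTRUE(single_receptor),
    include_background = isTRUE(include_background),
    min_locus_gap = as.numeric(min_locus_gap %||% (2 * insert_mean)),
    end_margin = as.numeric(end_margin %||% insert_mean)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_species, "species,", x$n_events, "events x",
      x$segments_per_event, "segments of", x$segment_length, "bp;",
      sprintf("%gX %dbp reads, insert %g+-%g, error %g, seed %d\n",
              x$depth, x$read_length, x$insert_mean, x$insert_sd,
              x$error_rate, x$seed))
  invisible(x)
}

#' Generate a set of synthetic reference genomes
#'
#' Draws `n_species` random nucleotide sequences with lengths uniform in
#' `genome_length_range`. Deterministic per seed.
#'
#' @param config a [sim_config()].
#' @return a named [Biostrings::DNAStringSet].
#' @export
generate_reference_set <- function(config) {
  if (config$n_species < 2)
    stopf("invalid config: n_species must be >= 2 (one receptor and one donor)")
  with_seed(derive_seed(config$seed, 1L), {
    lens <- sample_range(config$genome_length_range[1],
                         config$genome_length_range[2], config$n_species)
    seqs <- vapply(lens, random_dna, character(1))
  })
  names(seqs) <- sprintf("ref_%03d", seq_len(config$n_species))
  Biostrings::DNAStringSet(seqs)
}

# Entry/exit breakends of a transferred segment read in strain direction.
# dir "L" means the joined piece lies left of pos (ends there, read forward);
# "R" means it lies right of pos (starts there).
.seg_entry <- function(ref, s, e, o) {
  if (o == "+") list(ref = ref, pos = s, dir = "R") else list(ref = ref, pos = e, dir = "L")
}
.seg_exit <- function(ref, s, e, o) {
  if (o == "+") list(ref = ref, pos = e, dir = "L") else list(ref = ref, pos = s, dir = "R")
}

#' Plant HGT events into synthetic genomes
#'
#' Each event picks a receptor and, per transferred segment, a donor genome;
#' a `segment_length` bp region is copied (not excised) from the donor and
#' inserted at a receptor locus, in random orientation. The receptor sequence
#' with all its insertions is the *true local strain*. Ground truth tables
#' record every junction (breakpoint pair) and the segment structure of each
#' strain. Coordinates are 0-based half-open internally.
#'
#' @param genomes named `DNAStringSet` from [generate_reference_set()].
#' @param config a [sim_config()].
#' @return a list with elements `events` (one row per transferred segment),
#'   `truth_segments` (strain structure: strain_id, rank, source_ref, start,
#'   end, orientation, role), `truth_breakpoints` (one row per junction:
#'   event_id, seg_label, ref1, pos1, dir1, ref2, pos2, dir2), and
#'   `strain_seqs` (a `DNAStringSet` of the true local strains).
#' @export
plant_hgt_events <- function(genomes, config) {
  lens <- setNames(Biostrings::width(genomes), names(genomes))
  if (length(genomes) < 2) stopf("need at least 2 genomes (receptor + donor)")
  with_seed(derive_seed(config$seed, 2L), {
    ins_list <- vector("list", config$n_events * config$segments_per_event)
    loci_by_receptor <- list()
    used <- list()  # donor -> transferred intervals already drawn (all events)
    row <- 0L
    fixed_receptor <- NULL
    for (ev in seq_len(config$n_events)) {
      receptor <- if (config$single_receptor && !is.null(fixed_receptor))
        fixed_receptor else sample(names(genomes), 1L)
      fixed_receptor <- fixed_receptor %||% receptor
      rl_len <- lens[[receptor]]
      n_seg <- config$segments_per_event
      n_loci <- if (config$shared_locus) 1L else n_seg
      lo <- ceiling(config$end_margin); hi <- floor(rl_len - config$end_margin)
      if (hi <= lo)
        stopf("event generation failed: receptor %s (length %d) too short for insertion margins",
              receptor, rl_len)
      have <- loci_by_receptor[[receptor]] %||% numeric(0)
      loci <- integer(0)
      for (j in seq_len(n_loci)) {
        ok <- FALSE
        for (try in 1:1000) {
          p <- sample_range(lo, hi)
          if (all(abs(p - c(have, loci)) >= config$min_locus_gap)) { ok <- TRUE; break }
        }
        if (!ok)
          stopf("event generation failed: receptor %s cannot host another insertion locus",
                receptor)
        loci <- c(loci, p)
      }
      loci_by_receptor[[receptor]] <- c(have, loci)
      for (j in seq_len(n_seg)) {
        donor <- sample(setdiff(names(genomes), receptor), 1L)
        dl <- lens[[donor]]
        if (dl < config$segment_length)
          stopf("event generation failed: donor %s (length %d) shorter than segment_length %d",
                donor, dl, config$segment_length)
        s <- NA_integer_
        for (try in 1:100) {
          cand <- sample_range(0L, dl - config$segment_length)
          ivs <- used[[donor]]
          # transferred intervals never overlap (and keep a 200 bp guard so
          # distinct junctions cannot collapse into one another)
          clash <- !is.null(ivs) &&
            any(cand < ivs[, 2] + 200L & cand + config$segment_length + 200L > ivs[, 1])
          if (!clash) { s <- cand; break }
        }
        if (is.na(s))
          stopf("event generation failed: donor %s cannot host a non-overlapping interval", donor)
        used[[donor]] <- rbind(used[[donor]], c(s, s + config$segment_length))
        row <- row + 1L
        ins_list[[row]] <- data.table(
          event_id = sprintf("event_%02d", ev),
          seg_label = sprintf("event_%02d_seg_%d", ev, j),
          receptor = receptor,
          locus = if (config$shared_locus) loci[1L] else loci[j],
          chain_rank = j,
          donor = donor,
          dstart = s, dend = s + config$segment_length,
          orientation = sample(c("+", "-"), 1L)
        )
      }
    }
  })
  events <- rbindlist(ins_list)
  truth <- .build_truth(events, lens)
  strain_seqs <- .build_strain_seqs(truth$truth_segments, genomes)
  list(events = events, truth_segments = truth$truth_segments,
       truth_breakpoints = truth$truth_breakpoints, strain_seqs = strain_seqs)
}

# Assemble strain structure tables and junction truth from planted insertions.
.build_truth <- function(events, lens) {
  segs_list <- list(); bp_list <- list()
  for (rec in unique(events$receptor)) {
    ev <- events[receptor == rec][order(locus, chain_rank)]
    strain_id <- paste0(rec, "_hgt")
    segs <- list(); prev <- 0L; rank <- 0L
    loci <- unique(ev$locus)
    for (p in loci) {
      rank <- rank + 1L
      segs[[rank]] <- data.table(strain_id = strain_id, rank = rank, source_ref = rec,
                                 start = prev, end = p, orientation = "+",
                                 role = "receptor", event_id = NA_character_,
                                 seg_label = NA_character_)
      chain <- ev[locus == p]
      for (i in seq_len(nrow(chain))) {
        rank <- rank + 1L
        segs[[rank]] <- data.table(strain_id = strain_id, rank = rank,
                                   source_ref = chain$donor[i],
                                   start = chain$dstart[i], end = chain$dend[i],
                                   orientation = chain$orientation[i], role = "donor",
                                   event_id = chain$event_id[i],
                                   seg_label = chain$seg_label[i])
      }
      prev <- p
    }
    rank <- rank + 1L
    segs[[rank]] <- data.table(strain_id = strain_id, rank = rank, source_ref = rec,
                               start = prev, end = lens[[rec]], orientation = "+",
                               role = "receptor", event_id = NA_character_,
                               seg_label = NA_character_)
    segs <- rbindlist(segs)
    segs_list[[strain_id]] <- segs
    # junctions between consecutive strain segments at each insertion locus
    for (p in unique(ev$locus)) {
      chain <- ev[locus == p]
      nodes <- vector("list", nrow(chain) + 2L)
      nodes[[1]] <- list(ref = rec, pos = p, dir = "L")  # receptor piece ends at p
      for (i in seq_len(nrow(chain))) {
        nodes[[i + 1L]] <- list(
          entry = .seg_entry(chain$donor[i], chain$dstart[i], chain$dend[i], chain$orientation[i]),
          exit  = .seg_exit(chain$donor[i], chain$dstart[i], chain$dend[i], chain$orientation[i]),
          seg_label = chain$seg_label[i], event_id = chain$event_id[i])
      }
      nodes[[nrow(chain) + 2L]] <- list(ref = rec, pos = p, dir = "R")
      for (i in seq_len(nrow(chain) + 1L)) {
        up <- if (i == 1L) nodes[[1]] else nodes[[i]]$exit
        dn <- if (i == nrow(chain) + 1L) nodes[[nrow(chain) + 2L]] else nodes[[i + 1L]]$entry
        seg_up <- if (i > 1L) nodes[[i]]$seg_label else NA_character_
        seg_dn <- if (i <= nrow(chain)) nodes[[i + 1L]]$seg_label else NA_character_
        evid <- if (i <= nrow(chain)) nodes[[i + 1L]]$event_id else nodes[[i]]$event_id
        bp_list[[length(bp_list) + 1L]] <- data.table(
          event_id = evid, seg_up = seg_up, seg_dn = seg_dn,
          strain_id = strain_id,
          ref1 = up$ref, pos1 = up$pos, dir1 = up$dir,
          ref2 = dn$ref, pos2 = dn$pos, dir2 = dn$dir)
      }
    }
  }
  list(truth_segments = rbindlist(segs_list),
       truth_breakpoints = rbindlist(bp_list))
}

.build_strain_seqs <- function(truth_segments, genomes) {
  ids <- unique(truth_segments$strain_id)
  out <- vapply(ids, function(sid) {
    segs <- truth_segments[strain_id == sid][order(rank)]
    pieces <- vapply(seq_len(nrow(segs)), function(i) {
      s <- as.character(Biostrings::subseq(genomes[[segs$source_ref[i]]],
                                           start = segs$start[i] + 1L, end = segs$end[i]))
      if (segs$orientation[i] == "-") revcomp_chr(s) else s
    }, character(1))
    paste(pieces, collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(setNames(out, ids))
}

#' Simulate WGSIM-like paired-end reads
#'
#' Fragments are placed uniformly along each input sequence; fragment length
#' is Normal(`insert_mean`, `insert_sd`) truncated below at `2*read_length`
#' (and at the sequence length); mate 1 is the forward end, mate 2 the
#' reverse-complemented other end. Substitution errors occur per base at
#' `error_rate`; indels are not modelled. The number of pairs per sequence is
#' `round(depth * length / (2 * read_length))`.
#'
#' @param seqs named `DNAStringSet` (strains and, optionally, background
#'   references).
#' @param config a [sim_config()].
#' @param with_seq materialise read sequences (needed for FASTQ output; can
#'   be switched off for large coordinate-only benchmarks).
#' @return an object of class `hgt_readset`: list with `reads` (one row per
#'   read: qname, src, mate, rs, re, strand), `err` (read_row, offset in read
#'   orientation), `sequences` (character, if `with_seq`), and `read_length`.
#' @export
simulate_reads <- function(seqs, config, with_seq = TRUE) {
  lens <- setNames(Biostrings::width(seqs), names(seqs))
  rl <- config$read_length
  np <- pmax(0L, as.integer(round(config$depth * lens / (2 * rl))))
  short <- lens < config$insert_mean + 4 * config$insert_sd
  if (any(short))
    warnf("%d sequence(s) shorter than insert_mean + 4*insert_sd; fragments truncated",
          sum(short))
  n <- sum(np)
  with_seed(derive_seed(config$seed, 3L), {
    src <- rep(names(seqs), np)
    slen <- rep(unname(lens), np)
    flen <- pmin(slen, pmax(2L * rl, as.integer(round(rnorm(n, config$insert_mean,
                                                            config$insert_sd)))))
    fstart <- as.integer(floor(runif(n) * (slen - flen + 1)))
    pair_id <- seq_len(n)
    qname <- sprintf("%s_p%07d", src, pair_id)
    reads <- data.table(
      qname = rep(qname, 2L),
      src = rep(src, 2L),
      mate = rep(1:2, each = n),
      rs = c(fstart, fstart + flen - rl),
      re = c(fstart + rl, fstart + flen),
      strand = rep(c("+", "-"), each = n))
    nerr <- rbinom(2L * n, rl, config$error_rate)
    werr <- which(nerr > 0L)
    err <- if (length(werr)) {
      data.table(read_row = rep(werr, nerr[werr]),
                 offset = unlist(lapply(nerr[werr], function(k) sample.int(rl, k) - 1L)))
    } else data.table(read_row = integer(0), offset = integer(0))
    sequences <- NULL
    if (with_seq) {
      chr <- setNames(as.character(seqs), names(seqs))
      sequences <- substr(rep.int(chr[reads$src], 1L), reads$rs + 1L, reads$re)
      rev2 <- reads$mate == 2L
      sequences[rev2] <- revcomp_chr(sequences[rev2])
      if (nrow(err)) {
        bases <- c("A", "C", "G", "T")
        cur <- substr(sequences[err$read_row], err$offset + 1L, err$offset + 1L)
        repl <- vapply(cur, function(b) sample(setdiff(bases, b), 1L), character(1),
                       USE.NAMES = FALSE)
        for (i in seq_len(nrow(err))) {
          substr(sequences[err$read_row[i]], err$offset[i] + 1L,
                 err$offset[i] + 1L) <- repl[i]
        }
      }
    }
  })
  structure(list(reads = reads, err = err, sequences = sequences,
                 read_length = rl, with_seq = with_seq, src_names = names(seqs)),
            class = "hgt_readset")
}

#' Write a read set as paired FASTQ files
#'
#' @param readset from [simulate_reads()] (must carry sequences).
#' @param prefix output path prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq`.
#' @return the two file paths, invisibly.
#' @export
write_fastq <- function(readset, prefix) {
  if (!readset$with_seq) stopf("readset was simulated with with_seq = FALSE")
  qual <- strrep("I", readset$read_length)
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (m in 1:2) {
    idx <- which(readset$reads$mate == m)
    writeLines(paste0("@", readset$reads$qname[idx], "\n",
                      readset$sequences[idx], "\n+\n", qual),
               paths[m])
  }
  invisible(paths)
}

#' Emit ground-truth alignments for simulated reads
#'
#' Reports each read at its true position on the original references. A read
#' crossing a junction becomes a split record (primary + supplementary with
#' reciprocal soft clips) provided both parts reach `min_align_len` — the
#' minimum reportable alignment length of short-read aligners (BWA-MEM's
#' default output score threshold corresponds to ~30 bp); shorter overhangs
#' are soft-clipped on the primary record only. Pairs whose primary mates lie
#' on different references become junction pairs via the mate fields.
#'
#' @param readset from [simulate_reads()].
#' @param truth_segments strain structure table from [plant_hgt_events()]
#'   (maps strain coordinates to source references).
#' @param genomes the original reference `DNAStringSet`.
#' @param min_align_len minimum part length reported as an alignment.
#' @param as_table if `TRUE`, return the alignment record table directly (the
#'   same schema [load_alignments()] produces) instead of writing SAM.
#' @param path SAM output path (required when `as_table = FALSE`).
#' @return the record `data.table` (`as_table = TRUE`) or `path`, invisibly.
#' @export
emit_truth_alignments <- function(readset, truth_segments, genomes,
                                  min_align_len = 30L, as_table = FALSE,
                                  path = NULL) {
  rl <- readset$read_length
  reads <- copy(readset$reads)[, read_row := .I]
  glens <- setNames(Biostrings::width(genomes), names(genomes))
  # source maps: strain coords -> reference coords; genomes map to themselves
  smap_list <- list()
  if (!is.null(truth_segments) && nrow(truth_segments)) {
    ts <- as.data.table(truth_segments)[order(strain_id, rank)]
    ts[, w := end - start]
    ts[, sstart := cumsum(shift(w, fill = 0L)), by = strain_id]
    ts[, send := sstart + w]
    smap_list$strain <- ts[, .(src = strain_id, sstart, send, source_ref,
                               ref_start = start, ref_end = end, orientation)]
  }
  gsrc <- intersect(unique(reads$src), names(genomes))
  if (length(gsrc))
    smap_list$genome <- data.table(src = gsrc, sstart = 0L,
                                   send = unname(glens[gsrc]),
                                   source_ref = gsrc, ref_start = 0L,
                                   ref_end = unname(glens[gsrc]), orientation = "+")
  smap <- rbindlist(smap_list)
  unknown <- setdiff(unique(reads$src), smap$src)
  if (length(unknown))
    stopf("internal consistency error: reads from unknown source '%s'", unknown[1])
  setkey(smap, src, sstart, send)
  # map reads chunk-wise (pairs kept together) to bound transient memory;
  # chunking relies on simulate_reads' layout (mate-1 rows then mate-2 rows)
  n_pairs <- nrow(reads) %/% 2L
  paired_layout <- n_pairs > 0L && nrow(reads) == 2L * n_pairs &&
    identical(reads$mate, rep(1:2, each = n_pairs))
  chunk_pairs <- 250000L
  if (!paired_layout || n_pairs <= chunk_pairs) {
    out <- .emit_records_chunk(reads, readset$err, smap, rl, min_align_len)
    rec <- out$rec
    n_unmapped <- out$n_unmapped
  } else {
    starts <- seq(1L, n_pairs, by = chunk_pairs)
    rec_list <- vector("list", length(starts))
    n_unmapped <- 0L
    for (ci in seq_along(starts)) {
      i0 <- starts[ci]; i1 <- min(i0 + chunk_pairs - 1L, n_pairs)
      rows <- c(i0:i1, n_pairs + (i0:i1))
      out <- .emit_records_chunk(reads[rows], readset$err, smap, rl,
                                 min_align_len)
      rec_list[[ci]] <- out$rec
      n_unmapped <- n_unmapped + out$n_unmapped
    }
    rec <- rbindlist(rec_list)
  }
  if (n_unmapped)
    message(sprintf("emit_truth_alignments: %d read(s) with no part >= %d bp left unreported",
                    n_unmapped, min_align_len))
  setorder(rec, rname, pos, qname, supp)
  if (as_table) return(rec[, !"read_row"])
  if (is.null(path)) stopf("path is required when as_table = FALSE")
  seqf <- rep("*", nrow(rec)); qualf <- rep("*", nrow(rec))
  if (readset$with_seq) {
    seqf <- readset$sequences[rec$read_row]
    # SEQ must be on the reference forward strand; simulate_reads stores the
    # read in sequencing orientation, so reverse alignments get complemented
    need_rc <- rec$reverse
    seqf[need_rc] <- revcomp_chr(seqf[need_rc])
    qualf <- rep(strrep("I", rl), nrow(rec))
  }
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(glens), unname(glens)))
  body <- paste(rec$qname, rec$flag, rec$rname, rec$pos + 1L, rec$mapq, rec$cigar,
                ifelse(rec$mrnm == "*", "*", rec$mrnm),
                ifelse(rec$mpos < 0L, 0L, rec$mpos + 1L),
                rec$isize, seqf, qualf,
                paste0("NM:i:", rec$nm), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

# Map one chunk of reads (complete pairs) to truth alignment records.
.emit_records_chunk <- function(reads, err, smap, rl, min_align_len) {
  rq <- reads[, .(src, rs2 = rs, re2 = re - 1L, read_row)]
  setkey(rq, src, rs2, re2)
  parts <- foverlaps(rq, smap,
                     by.x = c("src", "rs2", "re2"),
                     by.y = c("src", "sstart", "send"), type = "any")
  # foverlaps is inclusive; drop zero-width touches at segment boundaries
  parts <- parts[rs2 < send & re2 + 1L > sstart]
  parts[, `:=`(x = pmax(rs2, sstart), y = pmin(re2 + 1L, send))]
  parts <- merge(parts, reads[, .(read_row, mate, rs, re, qname)], by = "read_row")
  parts[, w := y - x]
  parts[, fwd_seg := orientation == "+"]
  parts[, pstart := ifelse(fwd_seg, ref_start + (x - sstart), ref_start + (send - y))]
  parts[, pend := pstart + w]
  # read-orientation coordinates of the part
  parts[, prs := ifelse(mate == 1L, x - rs, re - y)]
  parts[, pre := prs + w]
  # alignment strand: forward iff segment orientation matches the mate's
  parts[, rev := fwd_seg != (mate == 1L)]
  kept <- parts[w >= min_align_len]
  n_unmapped <- length(setdiff(reads$read_row, kept$read_row))
  rm(parts)
  setorder(kept, read_row, -w, prs)
  kept[, part_rank := seq_len(.N), by = read_row]
  kept[, supp := part_rank > 1L]
  # per-part mismatch counts from planted error offsets
  kept[, nm := 0L]
  if (nrow(err)) {
    ek <- merge(err, kept[, .(read_row, part_rank, prs, pre)],
                by = "read_row", allow.cartesian = TRUE)
    ek <- ek[offset >= prs & offset < pre, .N, by = .(read_row, part_rank)]
    kept[ek, nm := i.N, on = c("read_row", "part_rank")]
  }
  # mate fields from the other mate's primary part
  prim <- kept[supp == FALSE,
               .(qname, mate, prname = source_ref, ppos = pstart,
                 pend = pend, prev = rev)]
  other <- prim[, .(qname, mate = 3L - mate, mrnm = prname, mpos = ppos,
                    mend = pend, mrev = prev)]
  kept <- merge(kept, other, by = c("qname", "mate"), all.x = TRUE)
  kept[is.na(mrnm), `:=`(mrnm = "*", mpos = -1L)]
  kept[, isize := 0L]
  same <- kept$mrnm == kept$source_ref & !kept$supp
  lo <- pmin(kept$pstart[same], kept$mpos[same])
  hi <- pmax(kept$pend[same], kept$mend[same])
  kept$isize[same] <- as.integer(ifelse(kept$pstart[same] <= kept$mpos[same],
                                        hi - lo, -(hi - lo)))
  # CIGAR in alignment orientation
  clipL <- ifelse(kept$rev, rl - kept$pre, kept$prs)
  clipR <- ifelse(kept$rev, kept$prs, rl - kept$pre)
  kept[, cigar := paste0(ifelse(clipL > 0L, paste0(clipL, "S"), ""),
                         w, "M",
                         ifelse(clipR > 0L, paste0(clipR, "S"), ""))]
  kept[, flag := 1L + 16L * rev + 32L * (!is.na(mrev) & mrev) +
         ifelse(mate == 1L, 64L, 128L) + 2048L * supp +
         8L * (mrnm == "*") +
         2L * (mrnm == source_ref & !supp)]
  rec <- kept[, .(qname, flag, rname = source_ref, pos = pstart, mapq = 60L,
                  cigar, mrnm, mpos, isize, nm,
                  rwidth = w, qstart = prs, qend = pre, read_len = rl,
                  reverse = rev, mreverse = !is.na(mrev) & mrev,
                  supp, secondary = FALSE, paired = TRUE, unmapped = FALSE,
                  first = mate == 1L, read_row)]
  list(rec = rec, n_unmapped = n_unmapped)
}

#' Run the whole simulator and write a benchmark data set
#'
#' Convenience wrapper: generates references, plants events, simulates reads
#' and writes `references.fasta`, `strains.fasta`, `reads_1/2.fastq`,
#' `truth.sam`, `truth_breakpoints.tsv` and `truth_strains.tsv` (TSV
#' coordinates 1-based inclusive).
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if missing).
#' @param min_align_len passed to [emit_truth_alignments()].
#' @return invisibly, a list with the in-memory objects (genomes, truth,
#'   readset, records table).
#' @export
simulate_hgt_dataset <- function(config, out_dir, min_align_len = 30L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genomes <- generate_reference_set(config)
  planted <- plant_hgt_events(genomes, config)
  pool <- planted$strain_seqs
  if (config$include_background) pool <- c(pool, genomes)
  readset <- simulate_reads(pool, config, with_seq = TRUE)
  Biostrings::writeXStringSet(genomes, file.path(out_dir, "references.fasta"))
  Biostrings::writeXStringSet(planted$strain_seqs, file.path(out_dir, "strains.fasta"))
  write_fastq(readset, file.path(out_dir, "reads"))
  emit_truth_alignments(readset, planted$truth_segments, genomes,
                        min_align_len = min_align_len,
                        path = file.path(out_dir, "truth.sam"))
  bp <- as.data.table(planted$truth_breakpoints)[, .(
    event_id, ref1, pos1 = pos1, strand1 = ifelse(dir1 == "L", "+", "-"),
    ref2, pos2 = pos2, strand2 = ifelse(dir2 == "L", "+", "-"))]
  fwrite(bp, file.path(out_dir, "truth_breakpoints.tsv"), sep = "\t")
  st <- as.data.table(planted$truth_segments)[, .(
    strain_id, rank, source_ref, start = start + 1L, end = end, orientation)]
  fwrite(st, file.path(out_dir, "truth_strains.tsv"), sep = "\t")
  invisible(list(genomes = genomes, planted = planted, readset = readset,
                 config = config))
}
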