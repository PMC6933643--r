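#' Load alignment records from SAM/BAM, keeping uniquely mapped reads
#'
#' Reads a SAM or BAM file (SAM input is converted with
#' [Rsamtools::asBam()]), drops unmapped records, secondary alignments and
#' records below `mapq_min` ("unique mapping" is operationalised as
#' `mapq >= mapq_min` and not secondary), and keeps supplementary records —
#' they carry the split-read evidence. Per-class drop counts are reported
#' via `message()`.
#'
#' Positions are converted to 0-based leftmost coordinates; `qstart`/`qend`
#' are the aligned query interval in original read orientation.
#'
#' @param path SAM or BAM file.
#' @param mapq_min minimum mapping quality (default 20).
#' @return a `data.table` with one row per retained record: qname, flag,
#'   rname, pos, mapq, cigar, mrnm, mpos, isize, nm, rwidth, qstart, qend,
#'   read_len, reverse, mreverse, supp, secondary, paired, unmapped, first.
#' @export
load_alignments <- function(path, mapq_min = 20L) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
  } else bam <- path
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar",
               "mrnm", "mpos", "isize"),
      tag = "NM"))[[1]]
  nm <- res$tag$NM %||% rep(NA_integer_, length(res$qname))
  dt <- data.table(qname = res$qname, flag = res$flag,
                   rname = as.character(res$rname), pos = res$pos - 1L,
                   mapq = res$mapq, cigar = res$cigar,
                   mrnm = as.character(res$mrnm), mpos = res$mpos - 1L,
                   isize = res$isize, nm = as.integer(nm))
  dt[, `:=`(paired = bitwAnd(flag, 1L) > 0L,
            unmapped = bitwAnd(flag, 4L) > 0L,
            reverse = bitwAnd(flag, 16L) > 0L,
            mreverse = bitwAnd(flag, 32L) > 0L,
            first = bitwAnd(flag, 64L) > 0L,
            secondary = bitwAnd(flag, 256L) > 0L,
            supp = bitwAnd(flag, 2048L) > 0L)]
  n0 <- nrow(dt)
  n_unmapped <- sum(dt$unmapped)
  n_secondary <- sum(!dt$unmapped & dt$secondary)
  n_mapq <- sum(!dt$unmapped & !dt$secondary & dt$mapq < mapq_min)
  dt <- dt[!unmapped & !secondary & mapq >= mapq_min]
  message(sprintf("load_alignments: %d records; dropped %d unmapped, %d secondary, %d mapq<%d; kept %d",
                  n0, n_unmapped, n_secondary, n_mapq, mapq_min, nrow(dt)))
  if (!nrow(dt)) {
    dt[, `:=`(rwidth = integer(0), qstart = integer(0), qend = integer(0),
              read_len = integer(0))]
    return(dt[])
  }
  cig <- dt$cigar
  rw <- GenomicAlignments::cigarWidthAlongReferenceSpace(cig)
  qw_aln <- GenomicAlignments::cigarWidthAlongQuerySpace(cig, after.soft.clipping = TRUE)
  qw_all <- GenomicAlignments::cigarWidthAlongQuerySpace(cig, after.soft.clipping = FALSE)
  clipL <- suppressWarnings(as.integer(sub("^([0-9]+)[SH].*$", "\\1", cig)))
  clipL[is.na(clipL) | !grepl("^[0-9]+[SH]", cig)] <- 0L
  clipR <- suppressWarnings(as.integer(sub("^.*[A-Z]([0-9]+)[SH]$", "\\1", cig)))
  clipR[is.na(clipR) | !grepl("[0-9]+[SH]$", cig)] <- 0L
  hardL <- ifelse(grepl("^[0-9]+H", cig),
                  as.integer(sub("^([0-9]+)H.*$", "\\1", cig)), 0L)
  hardR <- ifelse(grepl("[0-9]+H$", cig) & grepl("H$", cig),
                  as.integer(sub("^.*[A-Z]([0-9]+)H$", "\\1", cig)), 0L)
  read_len <- qw_all + hardL + hardR
  qstart <- ifelse(dt$reverse, clipR, clipL)
  dt[, `:=`(rwidth = rw, qstart = as.integer(qstart),
            qend = as.integer(qstart + qw_aln), read_len = as.integer(read_len))]
  dt[]
}

#' Extract junction pairs (mates on different references)
#'
#' A junction pair is a read pair whose two primary mates map to two
#' different references — the read-pair evidence for an HGT junction. The
#' reference pair is stored in canonical lexicographic order (`ref_x <
#' ref_y`) so that (X,Y) and (Y,X) coalesce; `pos_x`/`pos_y` are the mates'
#' leftmost coordinates.
#'
#' @param records record table from [load_alignments()] (or
#'   [emit_truth_alignments()] with `as_table = TRUE`).
#' @return `data.table`: qname, ref_x, pos_x, strand_x, ref_y, pos_y,
#'   strand_y.
#' @export
extract_junction_pairs <- function(records) {
  r <- records[supp == FALSE & secondary == FALSE & paired == TRUE &
                 unmapped == FALSE & !is.na(mrnm) & mrnm != "*"]
  n_star <- nrow(records[paired == TRUE & supp == FALSE & secondary == FALSE &
                           (is.na(mrnm) | mrnm == "*")])
  if (n_star) message(sprintf("extract_junction_pairs: %d record(s) with unmapped mate skipped", n_star))
  # each pair appears once as the record whose rname sorts before its mate's
  j <- r[rname != mrnm & rname < mrnm]
  j[, .(qname, ref_x = rname, pos_x = pos,
        strand_x = ifelse(reverse, "-", "+"),
        ref_y = mrnm, pos_y = mpos,
        strand_y = ifelse(mreverse, "-", "+"))]
}

#' Extract split reads (one read partitioned across two references)
#'
#' Pairs each supplementary record with its primary record (same read),
#' keeps splits whose two parts map to different references, and derives per
#' part the junction-side reference coordinate and its direction: `dir "L"`
#' means the aligned piece lies left of the coordinate (the alignment ends
#' there reading the reference forward), `"R"` that it lies right of it.
#' The matched-base count `m` of a part is its aligned query width minus the
#' record's NM value; splits with `min(m) < min_match` are discarded (each
#' part serves as the partner-scored e2 side in one scoring direction).
#'
#' @param records record table from [load_alignments()].
#' @param min_match minimum matched bases (default 15).
#' @return `data.table` with canonical sides a/b (`ref_a < ref_b`): qname,
#'   ref_a, coord_a, dir_a, m_a, l_a, ref_b, coord_b, dir_b, m_b, l_b.
#' @export
extract_split_reads <- function(records, min_match = 15L) {
  sup <- records[supp == TRUE]
  if (!nrow(sup)) return(.empty_splits())
  prim <- records[supp == FALSE & secondary == FALSE & unmapped == FALSE]
  m <- merge(sup, prim, by = c("qname", "first"), suffixes = c(".s", ".p"))
  n_orphan <- nrow(sup) - nrow(m)
  if (n_orphan)
    message(sprintf("extract_split_reads: %d supplementary record(s) without a primary partner skipped", n_orphan))
  m <- m[rname.s != rname.p]
  if (!nrow(m)) return(.empty_splits())
  part <- function(pos, rwidth, qstart, qend, reverse, nm, is_e1) {
    # junction-side coordinate of a part: the boundary adjacent to the split
    # in read order. e1 = earlier part of the read, e2 = later part.
    at_read_end <- is_e1   # e1's junction is at its read-order end
    fwd <- !reverse
    coord <- ifelse(at_read_end == fwd, pos + rwidth, pos)
    dir <- ifelse(at_read_end == fwd, "L", "R")
    list(coord = as.integer(coord), dir = dir,
         m = as.integer(qend - qstart - ifelse(is.na(nm), 0L, nm)),
         l = as.integer(qend - qstart))
  }
  p_first <- m$qstart.p <= m$qstart.s
  e1 <- list(); e2 <- list()
  take <- function(which_rec, is_e1) {
    sfx <- which_rec
    part(m[[paste0("pos.", sfx)]], m[[paste0("rwidth.", sfx)]],
         m[[paste0("qstart.", sfx)]], m[[paste0("qend.", sfx)]],
         m[[paste0("reverse.", sfx)]], m[[paste0("nm.", sfx)]], is_e1)
  }
  pp <- take("p", TRUE); ps <- take("p", FALSE)
  sp <- take("s", TRUE); ss <- take("s", FALSE)
  sel <- function(lst1, lst2, use1) {
    lapply(names(lst1), function(nm.) ifelse(use1, lst1[[nm.]], lst2[[nm.]]))
  }
  e1v <- sel(pp, sp, p_first); names(e1v) <- names(pp)
  e2v <- sel(ss, ps, p_first); names(e2v) <- names(ss)
  out <- data.table(qname = m$qname,
                    ref_1 = ifelse(p_first, m$rname.p, m$rname.s),
                    coord_1 = e1v$coord, dir_1 = e1v$dir, m_1 = e1v$m, l_1 = e1v$l,
                    ref_2 = ifelse(p_first, m$rname.s, m$rname.p),
                    coord_2 = e2v$coord, dir_2 = e2v$dir, m_2 = e2v$m, l_2 = e2v$l)
  n_low <- sum(pmin(out$m_1, out$m_2) < min_match)
  out <- out[pmin(m_1, m_2) >= min_match]
  if (n_low) message(sprintf("extract_split_reads: %d split(s) below min_match %d discarded",
                             n_low, min_match))
  swap <- out$ref_1 > out$ref_2
  res <- data.table(qname = out$qname,
                    ref_a = ifelse(swap, out$ref_2, out$ref_1),
                    coord_a = ifelse(swap, out$coord_2, out$coord_1),
                    dir_a = ifelse(swap, out$dir_2, out$dir_1),
                    m_a = ifelse(swap, out$m_2, out$m_1),
                    l_a = ifelse(swap, out$l_2, out$l_1),
                    ref_b = ifelse(swap, out$ref_1, out$ref_2),
                    coord_b = ifelse(swap, out$coord_1, out$coord_2),
                    dir_b = ifelse(swap, out$dir_1, out$dir_2),
                    m_b = ifelse(swap, out$m_1, out$m_2),
                    l_b = ifelse(swap, out$l_1, out$l_2))
  res[]
}

.empty_splits <- function() {
  data.table(qname = character(0), ref_a = character(0), coord_a = integer(0),
             dir_a = character(0), m_a = integer(0), l_a = integer(0),
             ref_b = character(0), coord_b = integer(0), dir_b = character(0),
             m_b = integer(0), l_b = integer(0))
}

#' Per-reference coverage profile from primary alignments
#'
#' @param records record table from [load_alignments()].
#' @param ref_lengths named integer vector of reference lengths.
#' @return an object of class `coverage_profile`: list with `cov` (a list of
#'   [S4Vectors::Rle] per reference) and `mean_cov` (depth averaged over the
#'   whole reference).
#' @export
coverage_profile <- function(records, ref_lengths) {
  prim <- records[supp == FALSE & secondary == FALSE & unmapped == FALSE]
  cov <- lapply(names(ref_lengths), function(r) {
    sub <- prim[rname == r]
    if (!nrow(sub)) return(S4Vectors::Rle(0L, ref_lengths[[r]]))
    ir <- IRanges::IRanges(start = sub$pos + 1L, width = sub$rwidth)
    IRanges::coverage(ir, width = ref_lengths[[r]])
  })
  names(cov) <- names(ref_lengths)
  structure(list(cov = cov,
                 mean_cov = vapply(cov, function(x) mean(as.numeric(x)), numeric(1)),
                 ref_lengths = ref_lengths),
            class = "coverage_profile")
}

#' Mean depth over an interval
#'
#' @param profile a [coverage_profile()].
#' @param ref reference name.
#' @param start,end 0-based half-open interval.
#' @return mean per-base depth over `[start, end)`.
#' @export
interval_coverage <- function(profile, ref, start, end) {
  if (!ref %in% names(profile$cov)) stopf("unknown reference '%s'", ref)
  if (!(start >= 0 && start < end && end <= profile$ref_lengths[[ref]]))
    stopf("invalid interval [%s, %s) on %s", start, end, ref)
  mean(as.numeric(S4Vectors::window(profile$cov[[ref]], start + 1L, end)))
}
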