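#' Estimate the average insert size from concordant pairs
#'
#' Robust location/scale of the absolute template lengths of concordant
#' primary pairs (same reference, non-zero TLEN): median and MAD-derived
#' standard deviation. With fewer than 100 usable pairs the supplied
#' fallback is returned with a warning.
#'
#' @param records alignment record table.
#' @param fallback value used when too few concordant pairs exist (`NULL`
#'   raises an error in that case).
#' @return list with `mean`, `sd`, `n`.
#' @export
estimate_insert_size <- function(records, fallback = NULL) {
  conc <- records[supp == FALSE & secondary == FALSE & unmapped == FALSE &
                    paired == TRUE & !is.na(mrnm) & mrnm == rname &
                    !is.na(isize) & isize > 0L]
  if (nrow(conc) < 100L) {
    if (is.null(fallback))
      stopf("only %d concordant pair(s): cannot estimate insert size (provide eps)",
            nrow(conc))
    warnf("only %d concordant pair(s): falling back to insert size %s",
          nrow(conc), fallback)
    return(list(mean = fallback, sd = NA_real_, n = nrow(conc)))
  }
  tl <- abs(conc$isize)
  list(mean = median(tl), sd = mad(tl), n = length(tl))
}

#' Run the full detection + reconstruction pipeline
#'
#' Executes the workflow stages in order: alignment ingestion (unique
#' mapping filter), junction-pair selection, DBSCAN clustering, exact
#' breakpoint positioning from split reads, reference segmentation with
#' coverage-based copy estimates, graph construction with dummy edges and
#' connectivity repair, integer balancing, and Eulerian traversal into
#' local strains. Stage artifacts are written under `out_dir` (1-based
#' inclusive coordinates in all TSVs).
#'
#' @param alignments SAM/BAM path or record table.
#' @param genomes reference FASTA path or `DNAStringSet`.
#' @param out_dir output directory (`NULL` = no files written).
#' @param eps DBSCAN radius; `NULL` = average insert size estimated from
#'   the data.
#' @param min_sample,min_match,mapq_min detection parameters.
#' @param min_segment_cov,min_segment_len,receptors segmentation
#'   parameters.
#' @return list with `breakpoints`, `graph`, `strains`, `sequences`,
#'   `structure`, `insert_size`, `solver`.
#' @export
run_hgt_pipeline <- function(alignments, genomes, out_dir = NULL, eps = NULL,
                             min_sample = 1L, min_match = 15L, mapq_min = 20L,
                             min_segment_cov = 0.5, min_segment_len = 50L,
                             receptors = NULL) {
  if (is.character(genomes)) genomes <- Biostrings::readDNAStringSet(genomes)
  names(genomes) <- sub("\\s.*$", "", names(genomes))
  records <- if (is.character(alignments)) load_alignments(alignments, mapq_min)
             else alignments
  ins <- if (is.null(eps)) estimate_insert_size(records) else list(mean = eps, sd = NA, n = NA)
  bps <- detect_breakpoints(records, eps = ins$mean, min_sample = min_sample,
                            min_match = min_match)
  message(sprintf("pipeline: %d breakpoint pair(s) called (%d precise)",
                  nrow(bps), sum(bps$precise)))
  recon <- reconstruct_strains(records, genomes, bps,
                               min_segment_cov = min_segment_cov,
                               min_segment_len = min_segment_len,
                               receptors = receptors)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    out_bp <- copy(bps)[, `:=`(pos1 = pos1, pos2 = pos2)]
    fwrite(out_bp, file.path(out_dir, "breakpoints.tsv"), sep = "\t")
    jp <- extract_junction_pairs(records)
    fwrite(jp[, .(qname, ref_x, pos_x = pos_x + 1L, strand_x,
                  ref_y, pos_y = pos_y + 1L, strand_y)],
           file.path(out_dir, "junction_pairs.tsv"), sep = "\t")
    sp <- suppressMessages(extract_split_reads(records, min_match = min_match))
    fwrite(sp, file.path(out_dir, "split_reads.tsv"), sep = "\t")
    if (!is.null(recon$graph)) {
      fwrite(recon$graph$segments[, .(seg_id, ref, start = start + 1L, end,
                                      role, cov, copy)],
             file.path(out_dir, "segments.tsv"), sep = "\t")
      fwrite(recon$graph$edges, file.path(out_dir, "graph.tsv"), sep = "\t")
    }
    if (length(recon$sequences))
      Biostrings::writeXStringSet(recon$sequences,
                                  file.path(out_dir, "strains.fasta"))
    if (nrow(recon$structure))
      fwrite(recon$structure[, .(strain_id, rank, source_ref,
                                 start = start + 1L, end, orientation, role)],
             file.path(out_dir, "strain_structure.tsv"), sep = "\t")
    if (!is.null(recon$solver))
      writeLines(sprintf("objective\t%s\nexact\t%s\nnodes\t%s",
                         recon$solver$objective, recon$solver$exact,
                         recon$solver$nodes),
                 file.path(out_dir, "solver_report.txt"))
  }
  list(breakpoints = bps, graph = recon$graph, strains = recon$strains,
       sequences = recon$sequences, structure = recon$structure,
       insert_size = ins, solver = recon$solver)
}
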