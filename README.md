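# hgtrecon

Detection of horizontal-gene-transfer (HGT) breakpoints in shotgun
metagenomic alignments, and reconstruction of the *local strains* — the
receptor genomes carrying donor segments spliced in at the HGT sites —
for microbiome researchers who want sequence-level structure, not just
event calls.

## What it computes

Given paired-end reads aligned against a multi-species reference set
(SAM/BAM), the pipeline:

1. keeps uniquely mapped reads and extracts **junction pairs** (mates on
   two references) and **split reads**;
2. clusters junction-pair coordinates per reference pair with **DBSCAN**
   (Euclidean distance, `eps` = average insert size, `min_sample = 1`);
3. refines each cluster to an exact breakpoint pair with a split-read
   scoring scheme: part quality `q_s = m/l` (minimum 15 matched bases) and
   position score `1 − Σ_s log(1 − q_s)`, highest combined score wins;
4. cuts references into segments, estimates copy numbers
   `c(v) = cov(v)/cov(r)`, and builds a bidirected segment graph whose
   edges carry copy numbers, plus dummy/chain edges closing the k strain
   paths into one circuit;
5. balances the graph with an exact integer program
   (`min Σ|c(u)−t(u)| + Σ|c(e)−t(e)|` subject to
   `c_in(u) = c(u) = c_out(u)`), finds an **Eulerian circuit**, and cuts
   it into strain walks `b_i → t_i`, emitting each strain's sequence and
   segment table.

A self-contained simulator (synthetic genomes, planted HGT events with
1–5 transferred segments of 10 kb, WGSIM-like reads, ground-truth
alignments and truth tables) plus the segment-level metrics —
Reconstruction Accuracy `RA = SW(h,H)/(m·match_score)` (token
Smith–Waterman, match 1 / mismatch −1 / gap 0, 20 bp boundary tolerance),
Detection Rate, breakpoint sensitivity and FDR — make the whole pipeline
testable without external data.

## Worked example

```r
library(hgtrecon)

cfg <- sim_config(n_species = 3, genome_length_range = c(40000, 45000),
                  n_events = 1, segment_length = 5000, depth = 30,
                  error_rate = 0, seed = 7, include_background = FALSE)
genomes <- generate_reference_set(cfg)
planted <- plant_hgt_events(genomes, cfg)
reads   <- simulate_reads(planted$strain_seqs, cfg)
records <- emit_truth_alignments(reads, planted$truth_segments, genomes,
                                 as_table = TRUE)
res <- run_hgt_pipeline(records, genomes)
res$breakpoints[, .(ref1, pos1, ref2, pos2, score, n_split, precise)]
#>       ref1  pos1    ref2  pos2    score n_split precise
#> 1: ref_002 14397 ref_003 18513 129.5356      14    TRUE
#> 2: ref_002 14397 ref_003 23513 127.4430      14    TRUE
res$structure
#>            strain_id rank source_ref start   end orientation           role
#> 1: ref_002_strain_1     1    ref_002     0 14397           + receptor_first
#> 2: ref_002_strain_1     2    ref_003 18513 23513           -          donor
#> 3: ref_002_strain_1     3    ref_002 14397 31716           +  receptor_last

evaluate_reconstruction(planted$truth_segments, planted$truth_breakpoints,
                        res$structure, res$breakpoints)
#> $ra → 1  $detection_rate → 1  $sensitivity → 1  $fdr → 0
```

The two breakpoint rows are the two junctions of the single transferred
segment: the donor interval `ref_003:[18513, 23513)` was inserted (in
reverse orientation, hence the `-`) at receptor position 14397 — the score
column is the split-read position score, `n_split` its read support. RA,
detection rate and sensitivity of 1 with FDR 0 mean the planted event was
recovered exactly; `res$sequences` is the full reconstructed strain
sequence (here byte-identical to the planted strain).

A thin command-line front-end with `simulate`, `detect`, `reconstruct`
and `all` subcommands lives at `inst/cli/hgtrecon.R`; the vignette
(`vignettes/local-strain-reconstruction.Rmd`) documents the model, the
parameters and the simulator's scope.

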