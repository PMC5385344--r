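# nbmine — nanobody discovery from phage-display deep sequencing

`nbmine` mines candidate antigen-binding nanobodies (VHH single variable
domains, ~120 aa) from paired-end amplicon sequencing of phage-display
selection outputs. Given two demultiplexed FASTQ sample pairs — one
selection on antigen-positive cells, one negative control — it produces a
ranked list of enriched sequence clusters and a synthesis-ready consensus
gene for each candidate. It is aimed at antibody-engineering and
repertoire-sequencing groups who want the full binding potential of an
immune library, not just the clones abundant enough to surface in a
pick-and-screen campaign.

## Method

1. **Read processing.** Mates are overlap-merged (minimum overlap 10 nt,
   maximum mismatch rate 25%, higher-quality base wins inside the overlap),
   filtered at mean Phred ≥ 38 and length ≥ 150 nt, oriented on the FR1/FR4
   PCR primers (IUPAC-aware, both strands), translated in frame +1 from the
   FR1 primer start, and discarded on frameshift, premature stop or
   ambiguous codon. The primer-encoded termini (7 residues each side, IMGT
   positions 1–7 and 122–128) are trimmed.
2. **Clustering.** Unique trimmed peptides from both samples are pooled and
   clustered greedily at a sequence-identity threshold *c* (slow/accurate
   regime, no length differences): sequences are sorted (length, pooled
   count, lexicographic) and each joins the best earlier representative
   with identity ≥ *c*, else founds a new cluster. Identity is
   alignment-based, max identical pairs over all global alignments divided
   by length. The working threshold *c* = 0.9 is calibrated on a labeled
   reference set by counting clusters that mix unrelated nanobodies across
   the grid 0.70–1.00 (`calibrate_thresholds()`).
3. **Enrichment.** With selection and control cluster counts
   *n*<sub>sel</sub>, *n*<sub>ctrl</sub> and validated totals
   *N*<sub>sel</sub>, *N*<sub>ctrl</sub>:

   *EF* = (*n*<sub>sel</sub> · *f*) / max(*n*<sub>ctrl</sub>, 1),  *f* = *N*<sub>ctrl</sub> / *N*<sub>sel</sub>

   Candidates satisfy *n*<sub>sel</sub> ≥ 10 and *EF* ≥ 10 (boundaries
   included). Hit rates are reported with exact Clopper–Pearson intervals.
4. **Consensus.** Per-column majority vote over each candidate cluster's
   equal-length members, weighted by selection-sample read counts, restores
   the primer-encoded flanks and reverse-translates with a most-frequent
   codon table — the vote captures the enriched clone while averaging away
   PCR and read errors.

A ground-truth simulator (`sim_config()`, `simulate_repertoire()`,
`simulate_reads()`) generates two-sample experiments with planted binder
lineages, heavy-tailed abundances and realistic error processes, so the
whole pipeline is testable end to end without external data.

## Worked example

Simulate a small experiment (100 lineages, 8 of them binders enriched
50-fold, 2 × 10⁴ read pairs per sample), run the pipeline, and score it
against the known truth:

```r
library(nbmine)
cfg   <- sim_config(n_lineages = 100, n_binders = 8, reads_per_sample = 2e4, seed = 42)
truth <- simulate_repertoire(cfg)
files <- attr(simulate_reads(truth, dir = tempfile()), "files")
run <- run_pipeline(list(
  samples = list(SEL  = list(r1 = files[["SEL_R1"]],  r2 = files[["SEL_R2"]]),
                 CTRL = list(r1 = files[["CTRL_R1"]], r2 = files[["CTRL_R2"]])),
  sel = "SEL", ctrl = "CTRL", identity = 0.9), quiet = TRUE)
print(run)
```

```
nbmine run
                                  metric   SEL  CTRL
                      Raw reads (counts) 20000 20000
                   Joined reads (counts) 19028 19004
                   Joinable fraction (%)    95    95
 Full-length nanobody sequences (counts) 13878 13785
               Unique sequences (counts)  9960 10247
           Fraction unique sequences (%)    72    74
clusters: 238 at identity 0.90; candidates: 27
```

About 95% of pairs merge; ~27% of merged reads are lost to primer
mismatches, frameshifts and stops (the simulator injects all three); and
the selection sample shows the diversity reduction expected from positive
selection (72% vs 74% unique). The top candidates:

```r
head(candidates(run$enrichment)[, c("cluster", "count_sel", "count_ctrl", "ef")], 4)
#>   cluster count_sel count_ctrl    ef
#> 1      25       281          4 69.78
#> 2      12       498          8 61.83
#> 3      28       230          4 57.11
#> 4     112       335          6 55.46

rec <- binder_recovery(run, truth)
#> binder recall: 8/8  — every planted binder lineage's cluster passes both gates

run$consensus$consensus_full[1]
#> "EVQLVESTCAIDWTPEDCFVWPNHDWNCEQSMAILPGDDWMCDRWNTWQQRYWIFIRSHT..."  (120 aa)
run$consensus$dna[1]     # synthesis-ready; translates back to the peptide exactly
```

Each stage is also available separately (`process_reads()`,
`peptide_tally()`, `cluster_peptides()`, `enrich_clusters()`,
`consensus_sequences()`, `calibrate_thresholds()`), and
`inst/cli/nbmine.R` exposes them as shell subcommands
(`simulate`, `process`, `cluster`, `enrich`, `consensus`, `calibrate`,
`run`).

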