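---
title: "Mining nanobody repertoires from phage-display deep sequencing"
author: "nbmine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining nanobody repertoires from phage-display deep sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A camelid immunized against a target antigen carries heavy-chain-only
antibodies whose single variable domains (nanobodies, VHH, ~120 residues)
can be cloned into a phage-display library. One round of selection on
antigen-expressing cells enriches phage displaying binders; a parallel
selection on antigen-negative cells provides the background. Deep
sequencing of both outputs (paired-end 2 x 250 nt, which covers the full
VHH coding sequence) turns binder discovery into a counting problem: a
clone enriched in the selection sample relative to the control is a
candidate binder, whether or not it would ever surface in a conventional
pick-and-screen campaign.

Three obstacles stand between raw reads and orderable candidate genes, and
this package is organized around them:

1. **Read errors.** PCR and sequencing introduce substitutions, frameshift
   indels and premature stops that inflate apparent diversity and mask true
   clones.
2. **Clonal relatedness.** Somatic variants of one B-cell lineage should be
   counted together; unrelated sequences must not be. This requires a
   sequence-identity threshold with an empirical justification.
3. **Inclusion criteria.** "Enriched" needs a definition that is robust to
   unequal sequencing depth and to clones absent from the control sample.

## Read processing

Mates are merged by scanning every suffix/prefix overlap of at least 10
bases and keeping the overlap with the lowest mismatch fraction (ties go to
the longer overlap); a pair whose best overlap exceeds a 25% mismatch rate
is discarded as unjoinable. Within the overlap the higher-quality base is
kept — quality `max(q1, q2)` where the mates agree, `|q1 - q2|` where they
disagree, the forward base on an exact tie; `N` never counts as a match and
always loses to a called base. The merge scan prunes an overlap as soon as
its mismatch count can no longer beat the admissible minimum, which leaves
the chosen overlap unchanged.

Merged reads with mean Phred below 38 or length below 150 nt are dropped,
then each read is turned into FR1-to-FR4 orientation by requiring the FR1
PCR primer (`GAGGTGCAGCTGGTGGAGTCT`, encoding EVQLVES) at the 5' end and
the reverse complement of the FR4 primer (`TGAGGAGACGGTGACCWGGGT`,
encoding T(L/Q)VTVSS; IUPAC `W` = A/T) at the 3' end, checking both
strands. Primer matching is exact by default; `max_primer_mismatches`
relaxes it. Translation runs in frame +1 from the first FR1 base; a read is
valid only if its length is a multiple of three (the FR4 end is in frame),
contains no stop codon and no `N`-containing codon. The first and last
seven residues — dictated by the primers, not the clone — are trimmed
before all downstream analysis, and a floor of 36 trimmed residues guards
against degenerate amplicons. The quality/length gate and the
primer/frame gates commute, so their order (quality first, here) does not
change which reads survive. Every input pair lands in exactly one bin
(validated, unjoinable, quality/length, orientation, frameshift, premature
stop, ambiguous), which is what makes the run summary table a closed
ledger.

## Clustering

Trimmed peptides from both samples are pooled into one tally of unique
sequences with per-sample read counts, then clustered greedily in the
slow/accurate regime with no length differences allowed, the standard
configuration of greedy incremental clustering tools for this task:

* sort unique peptides by length (descending), pooled count (descending),
  then lexicographically — a total order, so the partition is reproducible
  across runs and platforms;
* the first sequence founds cluster 0; each later sequence is compared to
  **all** earlier-founded representatives of the same length and joins the
  one with the highest identity at or above the threshold (ties to the
  lowest cluster id), else founds a new cluster.

Identity between two equal-length peptides is the maximum number of
identical aligned residue pairs over all global alignments, divided by the
length. With gaps unpenalized this maximum is the longest common
subsequence, so compensating-indel alignments are honored: two sequences
differing by an adjacent transposition score 9/10, not 8/10. The
implementation computes a per-letter-count upper bound and the gap-free
(Hamming) lower bound first and runs the dynamic program only when the
bounds straddle the decision; the dynamic program itself is banded, which
is exact whenever the true identity reaches the threshold because an
equal-length alignment with `M` matches never strays more than `L - M`
cells off the diagonal. None of these devices can change the partition;
the test suite checks the engine against a plain-R reference
implementation and against an edit-distance oracle.

Read counts are metadata: they carry through to clusters but never affect
the geometry. Clustering the samples jointly (rather than separately with
post-hoc matching) is a deliberate choice — it guarantees that a cluster's
selection and control counts refer to the same sequence neighborhood.

## Threshold calibration

The working threshold of 0.9 is justified empirically rather than assumed.
A labeled reference set of nanobodies (target antigen, source publication,
database submission) is clustered across the grid 0.70–1.00 in steps of
0.05 with the identical engine. Within each cluster, two members count as
related if they share any label, taken transitively (connected components);
members with all labels unknown relate to nothing. The number of clusters
containing unrelated members rises as the threshold drops — on both the
labeled families the simulator builds and on public data this becomes
noticeable below ~0.8–0.85 — while 0.9 keeps clusters homogeneous without
shattering clonal families. The transitive reading of "related" is one
defensible interpretation of pairwise label sharing; it is the weakest
claim consistent with the labels.

## Enrichment and candidate selection

Unequal sequencing depth is corrected by the factor
`f = N_ctrl / N_sel` of total validated sequence counts, applied to the
selection counts. The enrichment factor of a cluster is

    EF = (n_sel * f) / max(n_ctrl, 1)

The pseudocount applies only to the control side: clusters absent from the
control (the most interesting ones) get a finite EF, while clusters absent
from the selection sample get EF 0 and can never be candidates. A cluster
is a candidate when its raw selection count is at least 10 **and** its EF
is at least 10, boundaries included; the size gate uses the
pre-normalization count. Both gates are monotone: tightening either can
only remove candidates. No significance testing is layered on top — the
gates are the published inclusion criteria, and the package keeps them as
plain, auditable arithmetic.

Human-readable reports round half-up (so 1.2143 prints as 1.21, 25/28 as
89%) while machine outputs carry full precision; hit rates are reported
with exact (Clopper–Pearson) binomial intervals from beta quantiles.

## Consensus building

Because clusters contain only equal-length members, a per-column vote needs
no multiple alignment. The default weight is the selection-sample read
count of each unique member — the vote is meant to capture the enriched
clone and average away read errors, and candidates are selection-driven —
with a one-vote-per-unique-member mode for comparison. Ties go to the
representative's residue, then lexicographically, so the consensus is
invariant under member reordering. The trimmed consensus is completed with
the primer-encoded flanks (`EVQLVES` and `TLVTVSS`/`TQVTVSS`; `L` is the
default realization of the degenerate FR4 position, configurable) and
reverse-translated with a packaged most-frequent-codon table (E. coli) so
that translating the synthesis-ready DNA reproduces the peptide exactly.

## The simulator

Every pipeline stage is validated against ground truth generated by the
package itself; no external data are required. The generator emulates the
structure of a two-sample selection experiment:

* **Lineages.** Founder peptides share a framework scaffold (with 2%
  per-position drift) and carry three randomized CDR-like windows, placing
  unrelated lineages near 70% identity — the regime real nanobody
  frameworks occupy — and collisions at or above 0.95 identity trigger
  regeneration. Clonal variants differ from their founder by 1 to
  `ceiling(divergence * L)` substitutions (default divergence 0.05); the
  founder receives the largest clonal weight, as expansions of the parental
  clone dominate real lineages.
* **Abundances.** Lineage weights are heavy-tailed (log-normal, sd(log)
  1.25 by default; a Zipf alternative is available). Binder lineages
  jointly hold a small share of the control sample (`binder_base_share`,
  default 1% — binders are not special before selection on the antigen,
  which is also why real binder clusters are often absent from the control
  entirely) and `binder_enrichment` times that share of the selection
  sample, background renormalized. `binder_enrichment` is therefore the
  *realized* selection:control abundance ratio, which requires
  `binder_base_share * binder_enrichment < 1`; infeasible combinations are
  refused at configuration time.
* **Reads.** Each variant has a DNA template (random synonymous codons
  between the fixed primer ends). Reads are drawn multinomially, split into
  overlapping 250-nt mates on a random strand, and corrupted independently
  per mate with substitutions (default 0.005/base), per-read 1-nt indels
  (0.02), injected internal stop codons (0.01) and unrelated reverse mates
  (0.05). Qualities follow a constant Q40 profile or an optional linear 3'
  decay to Q20 so the mean-Q38 filter can be exercised in both directions.
  Every read id encodes its truth key, and a provenance table records each
  injected error.

The defaults — 440 lineages of which 40 are binders enriched 50-fold, 10
variants per lineage, 2 x 10^5 read pairs per sample — are the package's
standard validation conditions; at these settings the full
simulate-process-cluster-enrich-consensus cycle runs in about two minutes
on one CPU, every binder lineage's cluster passes both candidate gates, and
the consensus of those clusters reproduces the true majority peptide (the
acceptance script recomputes these numbers on every run).

What the simulator deliberately does **not** model: PCR chimeras and
template switching, sequencer-specific error spectra and quality-error
correlation (injected substitutions keep the profile quality), somatic
hypermutation hotspots, and barcode/adapter structure (inputs are
demultiplexed and adapter-free by contract). Passing tests therefore show
that the algorithms are correct under a faithful but idealized error
model, not that the thresholds are optimal for any particular instrument.

Two regimes of the simulator matter for interpreting results. With reads
far exceeding the number of true variants (the default validation setting)
nearly all variants are observed in both samples and unique-sequence
counts are dominated by error reads. The diversity-reduction signature of
selection — a lower unique fraction and larger mean cluster size in the
selection sample — emerges cleanly in the sampling-limited regime (reads
well below the variant count), which is where the corresponding tests
operate; at saturation the effect shrinks to noise level, which is itself
informative about when that summary statistic is meaningful.

## Numerical and degenerate-input choices

* Rounding in reports is half-up (`round_half_up()`), never banker's.
* All tie-breaks (input sort, best-cluster, consensus columns) are total
  and documented above.
* `N` never matches in overlap or primer comparison; codons containing `N`
  are rejected as ambiguous rather than guessed.
* Empty samples, empty clusters, empty threshold grids, zero totals and
  negative counts raise immediate input errors; a selection/control run
  aborts if either sample is empty, since enrichment is undefined without a
  control.
* Sequence identity of the empty string is an error, not 1.

## Limitations

* The clustering engine compares every sequence to every same-length
  representative (the accurate regime). It comfortably handles the
  ~3 x 10^5 unique peptides of the validation runs on one CPU; repertoires
  orders of magnitude larger would need the short-word index of a
  full CD-HIT-style engine, which is out of scope.
* Length-variable clustering (`s < 1`), nucleotide-level clustering and
  multi-round enrichment trajectories are not implemented.
* The candidate gates are the published fixed cutoffs; no false-discovery
  control is attempted, matching the source procedure.
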