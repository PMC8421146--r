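---
title: "Junction-level analysis of Cas9 editing outcomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Junction-level analysis of Cas9 editing outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(junctionscan)
```

## The measurement model

Translocation-capture sequencing (PEM-seq and its relatives) anchors a
biotinylated primer next to a Cas9 target site and recovers, for every
captured allele, the junction between the *bait* side (fixed near the
on-target cut) and a *prey* locus — elsewhere on the same chromosome, on
another chromosome, or on the delivery plasmid — plus full-length uncut
alleles. After deduplication, each row of the junction table is one editing
event. Everything in this package is defined on that table; read-level
primary processing (primers, barcodes, alignment) is upstream and out of
scope.

The guide is a 20-nt protospacer plus a 3-nt PAM. All coordinate logic uses
the canonical SpCas9 blunt-cut geometry: the cut falls between protospacer
positions 17 and 18, i.e. 3 bp 5' of the PAM. For a site occupying the
0-based half-open window `[start, start + 23)` this puts the cut boundary
at `start + 17` on plus-strand sites and `start + 6` on minus-strand
sites. PAM-flexible variants differ only in their PAM pattern: `NGG`
(SpCas9), `NGN` (Cas9-NG, SpG), `NNN` (SpRY), with `NRN`/`NYN` splitting
on the purine/pyrimidine identity of the second PAM base.

## Candidate sites and off-target hotspots

`enumerate_candidates()` scans every 23-nt window on both strands and keeps
windows whose protospacer portion is within `max_mismatches` (default 7,
i.e. "fewer than eight") Hamming mismatches of the guide and whose PAM
matches the pattern. Mismatches are counted over the 20-nt protospacer
only; PAM compatibility is a separate boolean, because PAM composition and
mismatch burden are reported as separate statistics downstream. Bulges are
not modelled — the candidate definition is pure Hamming distance. Matching
is delegated to `Biostrings::matchPattern()`, and the test suite holds the
output equal, row for row, to an independent sliding-window oracle on
hundreds of random genomes.

Hotspot calling then proceeds in three steps:

1. `exclude_proximal()` removes junctions within ±20 kb of the on-target
   cut on its chromosome — these are indels and resection products, not
   translocations.
2. `find_enriched_regions()` single-linkage clusters the remaining prey
   positions per reference at a gap threshold (default 100 bp) and keeps
   clusters with at least `min_junctions` members (default 2). This is a
   deterministic stand-in for a statistical peak caller: we deliberately
   do not model a Poisson background or q-values, because the decisive
   filter is the next step and a deterministic caller makes every test
   exact. Region summits are modal prey positions, leftmost on ties.
3. `call_hotspots()` calls a candidate iff **more than 3** junctions fall
   within ±`cut_window` of its presumable cut position and it has
   **fewer than 8** mismatches, excluding the on-target site itself.

`cut_window` (default 25 bp) is a genuine free parameter: the source
convention says "at the presumable cutting site" without a width, and
junction ends scatter around true cuts because of end resection. 25 bp is
comfortably wider than the simulated scatter (±10 bp) and much narrower
than the 100 bp region-clustering gap; it is exposed in the configuration.
When two overlapping candidates (e.g. a site and its reverse-complement
shadow) share one junction cluster, both are reported with an `ambiguous`
flag — the data cannot distinguish them, so the package does not pretend
to.

## Outcome taxonomy and metrics

`classify_junctions()` assigns each event exactly one class by distance
rules only (strand is recorded but unused):

| class | rule |
|---|---|
| uncut | no junction (germline allele) |
| plasmid_insertion | prey on the plasmid reference |
| indel | same chromosome, |prey − cut| ≤ 100 bp |
| large_deletion | same chromosome, 100 bp < |prey − cut| ≤ 20 kb |
| offtarget_translocation | prey within ±100 bp of a called off-target cut |
| general_translocation | everything else |

The 100 bp–20 kb zone is assigned to large deletions: the >100 bp
definition sets the lower edge and the ±20 kb proximal convention the
upper; same-chromosome junctions beyond 20 kb count as general
translocations. Editing efficiency is the percentage of non-uncut events —
this requires germline alleles in the denominator, which is why the
simulator emits uncut records explicitly. Plasmid insertions are counted
as edited alleles.

`plasmid_profile()` normalises plasmid junctions per 100,000 of either
*all editing events* or *on-target indels* — both denominators are in
circulation for this metric and the choice is a flag
(`denominator=`, default `"editing_events"`); the profile bins junction
positions at 100 bp across the backbone. `fold_change()` expresses a
variant's rate relative to a reference library.

`paired_compare()` is a two-sided Wilcoxon matched-pairs signed-rank test
on per-locus metric pairs: zero differences dropped, exact null for ≤ 25
untied informative pairs (the typical locus panel, n = 9, is deep in the
exact range), normal approximation with continuity correction beyond.
All-zero differences make the test undefined; that is reported as a
flagged non-significant result rather than an error.

## The CNN ranker

The predictor reimplements a compact convolutional classifier over one-hot
site matrices of shape 23 × 4 with channel order **A, T, C, G** (taken
literally from its stated input convention, not alphabetical):
convolution (32 filters, width 5) → batch normalisation → global max
pooling → dense(100) → dense(23) with dropout (0.3) → one sigmoid unit,
trained with binary cross-entropy for 30 epochs. Positives are observed
off-target 23-mers; negatives are random 23-mers rejection-sampled to
carry **at least 11** protospacer mismatches, generated 1:1 by default.
The filter count, kernel width, dropout rate, optimiser (Adam, 1e-3,
batch 32) and 80/20 evaluation split are unstated upstream and fixed here
at conventional values, all exposed in `cnn_config()`.

No deep-learning framework exists in the target environment, so the
network — forward pass, batch-norm statistics, max-pool argmax routing,
backpropagation and Adam — is implemented in vectorised base R. At this
input size (23 × 4, thousands of examples) that trains in seconds, and it
buys exact determinism: a fixed seed reproduces weights and history
bit-for-bit, which the test suite asserts. Training is joint across loci
(pooled positives); per-locus training is simply calling `cnn_train()` on
a subset. Reported losses are on the natural [0, 1] cross-entropy scale.

`predict_rank()` scores candidates and ranks by descending sigmoid score
with (chrom, start) tie-breaks; `recall_at_rank()` produces the monotone
step curve of true sites recovered in the top k, flagging truths absent
from the candidate list.

## The synthetic world

The generator emulates the study design, not the data's microscale
texture. Its defaults are one stated world:

- genome: 3 uniform-random chromosomes of 100 kb (large enough to hold a
  ±20 kb exclusion zone plus distal clusters; random background means
  incidental homologs can exist, which is fine because the brute-force
  scan defines candidate truth);
- planted sites: exact requested mismatch counts (positions uniform
  without replacement) and literal PAMs; the on-target is planted with 0
  mismatches and its canonical PAM; overlapping plantings are an error;
- outcome proportions (defaults 70% uncut, 15% indel, 4% large deletion,
  5% off-target translocation, 4% general translocation, 2% plasmid
  insertion — an efficient editor with appreciable off-target activity)
  drawn i.i.d. per event, n = 10,000 by default;
- geometry per class mirrors the classifier's rules; large-deletion prey
  distances are uniform on 150–15,000 bp (inside the 100 bp–20 kb band);
  off-target prey scatter is ±10 bp around the planted cut, a stand-in
  for resection jitter chosen to sit well inside the 25 bp calling
  window (no empirical dispersion is published; it is configurable);
- the plasmid carries a `CACC<protospacer>GTTT` U6-sgRNA cassette, and
  `plasmid_u6_frac` can concentrate insertions there to emulate
  PAM-flexible self-cleavage of the delivery vector.

What a green test establishes: the pipeline recovers what it was defined
to recover, on data satisfying its own geometric assumptions, at
multinomial sampling noise. What it does not establish: performance on
real chromatin (uneven breakage background, repeat-driven multimapping,
resection-length distributions, locus effects), nor any of the deposited
libraries' printed counts, which depend on hg38 and real sequencing depth
and are explicitly out of scope.

## Numerical and testing choices

- Binomial 99% acceptance bands for recovered proportions use the exact
  quantiles `qbinom(0.005/0.995, n, p)`; fold-change bands are the ratio
  bounds induced by the two exact intervals (conservative).
- The signed-rank oracle enumerates all 2^n sign assignments and doubles
  the inclusive tail, matching the exact-test convention; agreement is
  asserted to 1e-12 for n ≤ 10.
- Determinism: every stochastic function takes a seed and restores the
  caller's RNG state; pipeline reruns are compared by md5 and must be
  byte-identical, including the manifest (file checksums are keyed by
  basename for that reason).
- Degenerate inputs are contracts, not afterthoughts: empty junction
  tables flow through, contigs shorter than 23 nt are skipped with a
  warning, zero denominators and single-class training sets are errors.

## Known limitations

- No bulged (indel-containing) off-target sites; pure Hamming candidates.
- The enrichment stage has no significance model; with a very dense
  Cas9-independent background, the >3-junction rule alone controls calls.
- PAM validity is reported for hotspots but never used as a filter; the
  mismatch and junction-count rules are the only gates.
- Cross-variant site overlap uses ±100 bp cut-position proximity, not
  exact identity — coordinate jitter between libraries makes exact
  matching brittle, but proximity can merge genuinely distinct adjacent
  sites in repeat regions.
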