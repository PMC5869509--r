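---
title: "Matched-control analysis of retroviral integration sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matched-control analysis of retroviral integration sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(provsel)
```

## The problem

When a retrovirus integrates, the provirus lands at a single host-genome
base and its later transcriptional fate — stable expression or epigenetic
silencing — depends on the chromatin neighbourhood of that base. Comparing
where *stably expressed* proviruses sit (relative to genes, transcription
start sites, histone-modification peaks, chromatin-state segments) against
a proper null tells us which genomic compartments permit long-term
provirus expression. That comparison is the job of this package.

The experimental readout is a cohort of single-cell clones, each carrying
one provirus with a GFP reporter, scored for the percentage of GFP+ cells
at 30 and 60 days post infection (dpi). A clone with at least 90% GFP+
cells is called stably expressing (the threshold is inclusive). Clones
that stay stable are sequenced at the provirus–host junction, giving one
integration site per clone: the LTR-proximal base, with the provirus
orientation as its strand.

## The null model: restriction-matched random controls

Integration sites recovered by junction PCR are not a uniform sample of
the genome: the protocol digests genomic DNA with restriction enzymes, so
recoverable sites are constrained by their distance to the nearest
recognition site, and the junction fragment must map uniquely. A fair
null must share both constraints. The package builds it in two tiers:

* **umMRC** (uniquely mapped matched random control): for each
  integration site, random genomic positions are drawn by picking a
  recognition site of the enzyme panel uniformly genome-wide and
  offsetting it by the parent site's distance-to-recognition-site in a
  random direction. A candidate is kept only if (a) its own nearest
  recognition-site distance equals the parent's *exactly* and (b) its
  junction fragment passes a uniqueness filter. From a pool of 200
  accepted candidates (the default), 3 controls per site are drawn at
  random.
* **agMRC** (active-gene matched random control): per site, 1000 umMRC
  candidates are generated, each candidate's distance to the nearest
  active gene body is computed (0 inside a body), and the 3 candidates
  whose distance is most similar to the site's own are selected, ties at
  the selection boundary broken at random. Comparing sites against agMRCs
  asks whether regulatory-element proximity is explained by active-gene
  targeting alone.

Per-site *exact* distance matching is deliberately stronger than matching
the distance distribution cohort-wide: it implies distributional matching
and is directly testable (the suite asserts the match for 100% of
controls). The matched distance is measured to the nearest recognition
site of the configured panel genome-wide; when several enzymes were used,
the index is their union. The offset direction is uniform because the
junction chemistry is symmetric at this level of abstraction.

The uniqueness filter replaces genome-browser alignment with an explicit
scan suited to desk-scale genomes: a fragment is uniquely mappable when it
has exactly one full-length, ungapped occurrence at ≥ 98% identity
(mismatch budget `L - ceiling(0.98 L)`), counting both strands. The
junction fragment spans from the candidate position across the full
recognition motif; because the uniqueness of a fragment shorter than
20 bp is not meaningful, short spans are extended to a 20 bp minimum
before scanning (fragments below 20 bp passed directly to the filter are
simply rejected). Without that extension, any site closer than ~16 bp to
its recognition site — a common occurrence under 4-cutters — could never
receive a control, which would silently bias the null toward
recognition-distal positions.

## Active genes, merged segments, expression classes

A gene is called active if its TSS base lies inside an H3K4me3 peak, or
inside a `Tss` chromatin segment, or within 500 bp of the nearest CAGE
peak TSS. The three criteria are kept as separate flags (plus their
union) because they select slightly different gene sets. The CAGE peak
TSS is operationalized as the peak midpoint; CAGE peaks are narrow, and
the choice is configurable to the 5' end for tracks where that is more
appropriate. The H3K4me3 and Tss-segment criteria are strict membership
of the TSS base — distance 0, no window.

Chromatin-state segments use a 25-label vocabulary and are merged into
two groups: **Regulatory** (11 states: Tss, TssF, PromF, PromP, Enh,
EnhF, EnhW, EnhWF, DnaseD, DnaseU, FaireW) and **Active** (those 11 plus
Gen5, Elon, ElonW, ElonWF, Gen3, H4K20, Low — 18 states). Merging joins
overlapping and bookended intervals, so the merged tracks are disjoint
and the Regulatory base set is contained in the Active base set. The
vocabulary is configuration, not code, since state names are
dataset-specific.

Expression activity splits genes at RPKM 1: below it, class `NA`; at or
above it, quartiles Q1–Q4 of RPKM rank with ties resolved by stable input
order, so quartile sizes differ by at most one.

## Distances, orientation, inference

All coordinates are 0-based half-open (BED-native) throughout; 1-based
inputs can be converted at load time with `one_based = TRUE`. The
distance between a single-base position and a feature interval is the gap
to the nearest covered base, `max(start − pos, pos − (end − 1), 0)`, so
"inside" and "distance 0" coincide and both edges behave symmetrically.
Features on other chromosomes are never nearest; positions on chromosomes
lacking a track yield `NA` and are excluded with a message. TSS-relative
signed distances are positive downstream in the gene's reading direction.
A site inside overlapping genes is attributed to the gene with the
nearest TSS (deterministic, and the least arbitrary single-host rule);
orientation is sense when provirus and host-gene strands agree.

Targeting frequencies (sites versus controls, in/out of a feature) are
tested with an exact two-sided Fisher test using the probability-mass
ordering convention, computed from the hypergeometric likelihood with a
1e-7 relative slack for floating-point ties — never a chi-square
approximation, because cohort sizes here are a few dozen. Distances are
tested with the Wilcoxon signed-rank test on per-site differences. The
pairing reduces each site's three controls to their median before
differencing (robust, keeps n equal to the number of sites); a `"each"`
mode emitting one pair per control exists for sensitivity analysis but
inflates n and is not the default. Zero differences are dropped, ties get
average ranks; for up to 25 effective pairs the p-value is exact under
the 2^n sign-flip law (computed by convolution of the signed-rank
generating function, which handles tied ranks exactly), above that a
normal approximation with tie-corrected variance and continuity
correction takes over. Raw p-values are reported; a Benjamini–Hochberg
column is available behind a flag and off by default.

## What the synthetic-data generator emulates

The generator exists so that every downstream stage is exercised on data
with known ground truth, with no external downloads:

* `simulate_genome()` draws i.i.d. bases at 41% GC — enough to give the
  enzyme panel realistic recognition-site spacing (≈ 90 bp for
  NlaIII + MseI) and to make 20 bp fragments essentially always unique.
* `simulate_annotation()` places non-overlapping genes (default: 12 genes
  of 2–4 kb on a 3 × 100 kb genome, half active), covering ≈ 12% of the
  genome with gene bodies and ≈ 6% with active bodies. Every active TSS is
  covered, by construction, by an H3K4me3 peak, a `Tss` segment and a CAGE
  peak whose midpoint falls on the TSS base, so the three activity criteria
  agree unless `decouple_criteria` separates them. Enhancer segments are
  placed both inside and between genes; `Elon` and `Quies` segments give
  the segment track non-trivial merged groups. The sparse-gene default
  deliberately reproduces the qualitative geometry that makes the real
  analysis informative — random positions are typically kilobases from a
  TSS while gene-body integrations are close.
* `simulate_integrations()` is a four-component multinomial mixture:
  active-gene-body (bp-uniform over bodies), TSS-proximal (two-sided
  exponential signed offset), enhancer-proximal (two-sided exponential
  from the segment midpoint) and uniform background. Components are
  mutually exclusive per site, which keeps the model identifiable and
  recoverable; the generating component is recorded per site. Intragenic
  sites are sense with probability `p_sense`, all others uniform.
  The presets encode the three vector profiles as realized by stably
  expressed cohorts: `hiv_like` (p_in_gene 0.8, TSS scale 10 kb),
  `mlv_like` (TSS- and enhancer-proximal, antisense-leaning, p_sense
  0.25) and `aslv_like` (random-like, weak gene preference, sense-leaning,
  TSS-proximal mass 0.115 — the fraction of clones that escape silencing).
* `simulate_clones()` models silencing per clone as deterministic
  exponential decay, `%GFP+(t) = 100·exp(−λ_class·t)` plus Gaussian
  measurement noise, clipped to [0, 100]. The analysis consumes only
  %GFP+ per clone, so the simplest generative model reaching the cohort
  summary statistics suffices; no per-cell process is simulated. The
  `aslv_like` preset protects TSS-proximal clones (λ = 0) and silences the
  rest quickly, making the expected 30-dpi stable fraction exactly the
  TSS-proximal mixture mass, 0.115; `hiv_like` sets the gene-body rate to
  `−log(0.9)/60` so gene-body clones sit at the 90% threshold at 60 dpi
  (stable at 30 dpi, a coin flip at 60 — gradual silencing); `mlv_like`
  decays negligibly everywhere except the background class.

What the generator does *not* emulate: sequence-level integration motif
preferences, genome-scale gene and intergenic lengths, transcription-
factor-resolved chromatin states, per-cell silencing stochasticity, or
vector titre effects. Tests passing on this synthetic data therefore
demonstrate the correctness of the *computations* (matching, distances,
tests, summaries) and the recoverability of known biases at realistic
cohort sizes — not biological conclusions about any real genome.

## Numerical choices and degenerate inputs

* Malformed input lines (bad coordinates, unknown vector or state labels,
  out-of-range %GFP+) are fatal, never skipped: silently dropped records
  would corrupt the matched-control statistics.
* Candidate draws are rejection sampling with a `max_attempts` cap; a
  site whose matching is impossible (e.g. its distance exceeds what the
  chromosome offers) fails with an error naming the site.
* Recognition-site ties (a position equidistant from two sites) resolve
  to the smaller position; host-gene ties resolve by gene id; agMRC
  selection ties are broken uniformly at random under the seed, which the
  oracle tests treat as equivalence classes on |Δdistance|.
* All generators and control samplers restore the caller's RNG state and
  derive per-site streams from the sorted site ids, so results are
  bit-reproducible and invariant to input row order.
* An all-zero 2×2 table, an all-zero difference vector, an empty position
  set and an empty clone cohort are errors, not silent NAs.

## Problem sizes used by the test suite

The packaged checks run on a 3 × 100 kb genome with the default
annotation and the NlaIII + MseI panel: control invariants on 50 sites
with pools of 100 (umMRC) and 200 (agMRC) candidates; Fisher oracle
agreement over all 2×2 tables with N ≤ 40 and signed-rank oracle
agreement over all sign patterns with n ≤ 12; null calibration over 400
replicates of 46 sites with 3 controls each; power over 200 replicates of
45 sites (umMRC pools of 5) and bias recovery over 100 replicates of 1000
sites; cohort demonstrations at the study sizes 46/45/32 sites and
2128/378/239 clones. Pool sizes below the protocol defaults only shrink
the candidate sets, not the matching rules, and none of the invariants
depend on them.

## Known limitations

* Uniqueness is ungapped identity; indel-mediated near-duplicates are
  outside the model (appropriate for i.i.d. synthetic genomes, not for
  repeat-rich real ones).
* The exact signed-rank path is O(n · Σranks) per test; for cohorts far
  beyond the exact limit the normal approximation is used, as is
  standard.
* The clone model's measurement noise is homoscedastic and Gaussian;
  FACS measurement error near 0% and 100% is not.
* `read_gene_table()` expects the simplified gene schema; full
  refGene/BED12 exon structure is intentionally out of scope.
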