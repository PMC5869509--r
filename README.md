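# provsel

Genomic and epigenomic analysis of retroviral provirus integration sites
against restriction-matched random controls.

## The problem

Retroviral vectors (ASLV-, HIV- and MLV-derived) integrate non-randomly,
and the chromatin around an integrated provirus decides whether its
expression stays stable or is epigenetically silenced. Given cohorts of
integration sites from long-term stably expressing single-cell clones,
the question is *where* those proviruses sit — inside genes? near active
transcription start sites (TSS)? near enhancers and regulatory chromatin
segments? — compared with a null that shares the recovery biases of the
junction-PCR protocol.

`provsel` implements that analysis end to end for anyone studying
integration-site selection or vector safety:

* **Matched random controls.** For each site, umMRCs — random positions
  whose distance to the nearest restriction-enzyme recognition site
  equals the site's own distance *exactly* and whose junction fragment is
  uniquely mappable (single full-length occurrence at ≥ 98% identity,
  both strands); 3 selected per site from a 200-candidate pool. agMRCs
  add matching on the distance to the nearest active gene (3 best of
  1000 candidates).
* **Annotation features.** Active-gene calls from three evidence classes
  (TSS inside an H3K4me3 peak, inside a `Tss` chromatin segment, or
  within 500 bp of a CAGE peak TSS); 25-state chromatin segments merged
  into Active (18 states) and Regulatory (11 states) groups; RPKM
  activity classes (NA, Q1–Q4).
* **Distances and targeting.** Nearest-feature distances (0 inside an
  interval, gap to the nearest covered base otherwise), signed
  TSS-relative positions, in-feature fractions, host-gene assignment and
  sense/antisense orientation.
* **Exact inference.** Two-sided Fisher test on the 2×2 targeting table
  (probability-mass ordering, exact hypergeometric) and the Wilcoxon
  signed-rank test on per-site distance differences (each site paired
  with the median of its own 3 controls; exact sign-flip law up to
  n = 25, tie-corrected normal approximation above).
* **Clonal stability.** Per-clone %GFP⁺ trajectories summarized into
  stable/silenced calls (≥ 90% GFP⁺, inclusive) per vector and
  timepoint, with both initial-cohort and conditional denominators.
* **Synthetic data.** Generators for genomes, annotation tracks, biased
  integration cohorts (`aslv_like`, `hiv_like`, `mlv_like` presets) and
  clone-silencing trajectories, so the complete pipeline runs with no
  downloads and known ground truth.

All coordinates are 0-based half-open (BED-native) throughout; loaders
accept standard BED/TSV/CSV/FASTA with a `one_based` escape hatch.

## Worked example

```r
library(provsel)

# simulate a study: genome, annotation, an HIV-like cohort of 45 sites
genome <- simulate_genome(n_chroms = 3, chrom_length = 100000, seed = 20)
ann    <- simulate_annotation(genome, seed = 21)
sites  <- simulate_integrations(ann, integration_bias("hiv_like"),
                                n = 45, vector = "HIV", seed = 22)

# restriction-matched random controls (3 per site)
index <- scan_recognition_sites(genome, restriction_motifs(c("NlaIII", "MseI")))
um    <- generate_ummrc(sites, index, genome,
                        control_params(n_candidates_um = 50), seed = 23)

# targeting frequency: sites vs controls, in/out of gene bodies
genes <- ann$genes
fs <- in_feature_fraction(sites, genes)
fc <- in_feature_fraction(um, genes)
cat(sprintf("in-gene: sites %.1f%%, umMRC %.1f%%\n",
            100 * fs$fraction, 100 * fc$fraction))
print(compare_targeting(fs$count_in, nrow(sites), fc$count_in, nrow(um)))

# distance to the nearest TSS, paired per site (median of its 3 controls)
ds <- nearest_tss_distance(sites, genes)
dc <- nearest_tss_distance(um, genes)
dc$parent_site_id <- um$parent_site_id
print(compare_distances(pair_site_controls(ds, dc)))

# clone silencing: 2128 ASLV clones, stable fraction at 30/60 dpi
aslv <- simulate_integrations(ann, integration_bias("aslv_like"),
                              n = 2128, vector = "ASLV", seed = 24)
clones <- simulate_clones(aslv, silencing_model("aslv_like"), seed = 25)
print(summarize_stability(clones))
```

Output:

```
in-gene: sites 82.2%, umMRC 14.8%
Fisher's exact test for count data (two-sided)
  statistic = 26.59375, p = < 2.2e-16, n = 180
Wilcoxon signed rank test (normal approximation)
  statistic = 170, p = 8.974e-05, n = 45
  vector timepoint denominator n_total n_stable fraction_stable
1   ASLV        30     initial    2128      248       0.1165414
2   ASLV        60     initial    2128      248       0.1165414
3   ASLV        60 conditional     248      248       1.0000000
```

Reading it: the HIV-like cohort sits inside genes far more often than its
matched controls (82% vs 15%; the Fisher statistic is the sample odds
ratio) and significantly closer to TSSs than the per-site control medians
(signed-rank V = 170 over n = 45 pairs). The ASLV-like clone cohort is
heavily silenced: only ~11.7% of 2128 clones remain ≥ 90% GFP⁺ at 30 dpi
(TSS-proximal proviruses escape), and every clone still stable at 30 dpi
stays stable at 60 dpi under the ASLV preset.

See `vignettes/integration-site-analysis.Rmd` for the model and design
choices, and the roxygen help pages for each function.

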