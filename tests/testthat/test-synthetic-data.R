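test_that("genome simulation is reproducible with the requested composition", {
  g1 <- simulate_genome(3L, 10000L, seed = 1L)
  g2 <- simulate_genome(3L, 10000L, seed = 1L)
  expect_identical(as.character(g1), as.character(g2))
  expect_equal(length(g1), 3L)
  expect_equal(names(g1), c("chr1", "chr2", "chr3"))

  g <- simulate_genome(1L, 100000L, gc_content = 0.5, seed = 2L)
  comp <- Biostrings::alphabetFrequency(g[[1L]])
  gc <- sum(comp[c("C", "G")]) / sum(comp[c("A", "C", "G", "T")])
  expect_gte(gc, 0.48)
  expect_lte(gc, 0.52)
})

test_that("annotation construction couples the three activity criteria", {
  fx <- study_fixture()
  ann <- fx$annotation
  genes <- ann$genes
  expect_true(all(genes$rpkm[!genes$active] == 0))
  expect_true(all(genes$rpkm[genes$active] > 0))
  # genes do not overlap
  o <- order(genes$chrom, genes$start)
  same <- genes$chrom[o][-1L] == genes$chrom[o][-nrow(genes)]
  expect_true(all(genes$start[o][-1L][same] >=
                    genes$end[o][-nrow(genes)][same]))
  # every active TSS carries all three evidence tracks at distance 0
  calls <- call_active_genes(genes,
                             h3k4me3_peaks = ann$peaks$H3K4me3,
                             tss_segments = ann$segments,
                             cage_peaks = ann$cage)
  expect_equal(calls$active_any, genes$active)
  expect_equal(calls$active_by_h3k4me3, genes$active)
  expect_equal(calls$active_by_tss_segment, genes$active)
  expect_equal(calls$active_by_cage, genes$active)
  # every Tss segment covers at least one active TSS
  tss_segs <- ann$segments[ann$segments$state == "Tss", , drop = FALSE]
  act <- genes[genes$active, , drop = FALSE]
  covered <- vapply(seq_len(nrow(tss_segs)), function(i) {
    any(act$chrom == tss_segs$chrom[i] & act$tss >= tss_segs$start[i] &
          act$tss < tss_segs$end[i])
  }, logical(1L))
  expect_true(all(covered))
  # segment track is disjoint
  s <- sort_intervals(ann$segments)
  same <- s$chrom[-1L] == s$chrom[-nrow(s)]
  expect_true(all(s$start[-1L][same] >= s$end[-nrow(s)][same]))
})

test_that("decoupling the criteria leaves CAGE-only active genes", {
  g <- simulate_genome(3L, 100000L, seed = 31L)
  ann <- simulate_annotation(g, annotation_params(decouple_criteria = TRUE),
                             seed = 32L)
  calls <- call_active_genes(ann$genes,
                             h3k4me3_peaks = ann$peaks$H3K4me3,
                             tss_segments = ann$segments,
                             cage_peaks = ann$cage)
  cage_only <- calls$active_by_cage & !calls$active_by_h3k4me3 &
    !calls$active_by_tss_segment
  expect_gt(sum(cage_only), 0L)
  expect_equal(calls$active_any, ann$genes$active)
})

test_that("an inactive annotation yields empty evidence tracks", {
  g <- simulate_genome(1L, 50000L, seed = 33L)
  ann <- simulate_annotation(g, annotation_params(n_genes = 4L,
                                                  active_fraction = 0,
                                                  n_enhancers = 0L),
                             seed = 34L)
  expect_equal(nrow(ann$cage), 0L)
  expect_equal(nrow(ann$peaks$H3K4me3), 0L)
  expect_false("Tss" %in% ann$segments$state)
})

test_that("integration bias components place sites where they claim", {
  fx <- study_fixture()
  ann <- fx$annotation
  act <- ann$genes[ann$genes$active, , drop = FALSE]

  all_genic <- simulate_integrations(
    ann, integration_bias(p_in_gene = 1), 200L, seed = 41L)
  expect_true(all(point_in_intervals(all_genic$chrom, all_genic$pos, act)))

  sense_only <- simulate_integrations(
    ann, integration_bias(p_in_gene = 1, p_sense = 1), 100L, seed = 42L)
  expect_true(all(classify_orientation(sense_only, ann$genes) == "sense"))

  # no bias: in-gene fraction approximately the genic genome fraction
  unif <- simulate_integrations(ann, integration_bias(), 2000L, seed = 43L)
  genic_frac <- sum(ann$genes$end - ann$genes$start) / sum(ann$chrom_lengths)
  frac <- in_feature_fraction(unif, ann$genes)$fraction
  ci <- qbinom(c(0.0005, 0.9995), 2000L, genic_frac) / 2000
  expect_gte(frac, ci[1L])
  expect_lte(frac, ci[2L])

  s1 <- simulate_integrations(ann, integration_bias("mlv_like"), 50L,
                              "MLV", seed = 44L)
  s2 <- simulate_integrations(ann, integration_bias("mlv_like"), 50L,
                              "MLV", seed = 44L)
  expect_identical(s1, s2)
})

test_that("clone decay follows the closed form and the seed", {
  sites <- make_sites("chr1", c(10L, 20L), vector = "ASLV")
  sites$component <- c("near_tss", "background")
  m <- silencing_model(lambda_by_class = c(near_active_tss = 0,
                                           background = 0.1),
                       measurement_noise_sd = 0)
  cl <- simulate_clones(sites, m, timepoints = 30L, seed = 51L)
  expect_equal(cl$dpi30, c(100, 100 * exp(-3)), tolerance = 1e-12)

  m0 <- silencing_model(lambda_by_class = c(near_active_tss = 0,
                                            background = 0),
                        measurement_noise_sd = 0)
  cl0 <- simulate_clones(sites, m0, timepoints = c(30L, 60L))
  expect_true(all(cl0$dpi30 == 100 & cl0$dpi60 == 100))

  mn <- silencing_model(lambda_by_class = c(near_active_tss = 0.01,
                                            background = 0.02),
                        measurement_noise_sd = 3)
  expect_identical(simulate_clones(sites, mn, seed = 52L),
                   simulate_clones(sites, mn, seed = 52L))
  sites$component[2L] <- "near_enhancer"
  expect_error(simulate_clones(sites, m, seed = 1L), "no silencing rate")
})

test_that("in-gene probability is recovered from large cohorts", {
  fx <- study_fixture()
  ann <- fx$annotation
  act <- ann$genes[ann$genes$active, , drop = FALSE]
  bias <- integration_bias(p_in_gene = 0.8)
  ok <- vapply(1:60, function(r) {
    s <- simulate_integrations(ann, bias, 1000L, seed = 6000L + r)
    abs(in_feature_fraction(s, act)$fraction - 0.8) <= 0.05
  }, logical(1L))
  expect_gte(mean(ok), 0.95)
})

test_that("synthetic study files round-trip through the io layer", {
  g <- simulate_genome(1L, 50000L, seed = 61L)
  ann <- simulate_annotation(g, annotation_params(n_genes = 5L), seed = 62L)
  sites <- simulate_integrations(ann, integration_bias(), 10L, "HIV",
                                 seed = 63L)
  clones <- simulate_clones(sites, silencing_model("hiv_like"), seed = 64L)
  d <- tempfile()
  write_synthetic_data(g, ann, d, sites = sites, clones = clones)
  g2 <- Biostrings::readDNAStringSet(file.path(d, "genome.fa"))
  expect_equal(as.character(g2[[1L]]), as.character(g[[1L]]))
  genes2 <- read_gene_table(file.path(d, "genes.tsv"))
  expect_equal(genes2$tss, ann$genes$tss[order(ann$genes$chrom,
                                               ann$genes$start)])
  sites2 <- read_sites(file.path(d, "sites.tsv"))
  expect_equal(sites2$pos, sites$pos)
  clones2 <- read_clone_table(file.path(d, "clones.csv"))
  expect_equal(clones2$dpi30, clones$dpi30, tolerance = 1e-6)
})
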