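test_that("active-gene calling applies the three criteria independently", {
  genes <- make_genes(c("g1", "g2", "g3"), "chr1",
                      c(1000L, 5000L, 9000L), c(3000L, 7000L, 9500L),
                      c("+", "+", "+"))
  # g1: H3K4me3 only; g2: CAGE at 400 bp; g3: nothing
  peaks <- data.frame(chrom = "chr1", start = 900L, end = 1100L)
  cage <- data.frame(chrom = "chr1", start = 5395L, end = 5406L)  # mid 5400
  calls <- call_active_genes(genes, h3k4me3_peaks = peaks,
                             cage_peaks = cage)
  expect_equal(calls$active_by_h3k4me3, c(TRUE, FALSE, FALSE))
  expect_equal(calls$active_by_tss_segment, rep(FALSE, 3L))
  expect_equal(calls$active_by_cage, c(FALSE, TRUE, FALSE))
  expect_equal(calls$active_any, c(TRUE, TRUE, FALSE))
})

test_that("the CAGE window boundary is inclusive at exactly 500 bp", {
  gene <- make_genes("g1", "chr1", 1000L, 2000L, "+")
  at <- function(mid) {
    cage <- data.frame(chrom = "chr1", start = mid - 5L, end = mid + 6L)
    call_active_genes(gene, cage_peaks = cage)$active_by_cage
  }
  expect_true(at(1500L))    # |d| = 500
  expect_false(at(1501L))   # |d| = 501
  # 5' end reference instead of midpoint
  cage <- data.frame(chrom = "chr1", start = 1400L, end = 3000L)
  expect_true(call_active_genes(gene, cage_peaks = cage,
                                cage_point = "five_prime")$active_by_cage)
})

test_that("TSS-base membership in peaks and Tss segments is exact", {
  # minus-strand gene: TSS = end - 1
  gene <- make_genes("g1", "chr1", 1000L, 2000L, "-")
  seg_cover <- data.frame(chrom = "chr1", start = 1999L, end = 2100L,
                          state = "Tss")
  seg_miss <- data.frame(chrom = "chr1", start = 2000L, end = 2100L,
                         state = "Tss")
  seg_other <- data.frame(chrom = "chr1", start = 1900L, end = 2100L,
                          state = "Enh")  # filtered out: not a Tss segment
  expect_true(call_active_genes(gene,
                                tss_segments = seg_cover)$active_by_tss_segment)
  expect_false(call_active_genes(gene,
                                 tss_segments = seg_miss)$active_by_tss_segment)
  expect_false(call_active_genes(gene,
                                 tss_segments = seg_other)$active_by_tss_segment)
})

test_that("segment merging respects group membership and bookends", {
  segs <- data.frame(chrom = "chr1",
                     start = c(100L, 200L, 0L, 40L, 400L),
                     end = c(200L, 300L, 50L, 90L, 500L),
                     state = c("Enh", "EnhF", "Tss", "PromF", "Quies"),
                     stringsAsFactors = FALSE)
  reg <- merge_chromatin_segments(segs, segment_group("Regulatory"))
  expect_equal(reg$start, c(0L, 100L))
  expect_equal(reg$end, c(90L, 300L))    # bookended + overlapping merged
  expect_false(any(reg$start <= 400L & 400L < reg$end))  # Quies dropped

  act <- merge_chromatin_segments(segs, segment_group("Active"))
  expect_error(
    merge_chromatin_segments(data.frame(chrom = "chr1", start = 0L,
                                        end = 10L, state = "Banana"),
                             segment_group("Active")),
    "unknown chromatin state")
})

test_that("regulatory bases are a subset of active bases", {
  expect_true(all(REGULATORY_STATES %in% ACTIVE_STATES))
  expect_length(chromatin_state_vocabulary(), 25L)
  expect_length(ACTIVE_STATES, 18L)
  expect_length(REGULATORY_STATES, 11L)
  fx <- study_fixture()
  segs <- fx$annotation$segments
  reg <- merge_chromatin_segments(segs, segment_group("Regulatory"))
  act <- merge_chromatin_segments(segs, segment_group("Active"))
  # every Regulatory base is covered by the Active track
  if (nrow(reg) > 0L) {
    probes <- data.frame(chrom = rep(reg$chrom, 2L),
                         pos = c(reg$start, reg$end - 1L))
    expect_true(all(point_in_intervals(probes$chrom, probes$pos, act)))
  }
  # coverage conservation: member-state segment bases are covered by the
  # merged track and vice versa (spot-check at all segment boundaries)
  mem <- segs[segs$state %in% REGULATORY_STATES, , drop = FALSE]
  probes <- data.frame(chrom = rep(mem$chrom, 2L),
                       pos = c(mem$start, mem$end - 1L))
  expect_true(all(point_in_intervals(probes$chrom, probes$pos, reg)))
  out_probes <- data.frame(chrom = reg$chrom, pos = reg$start)
  expect_true(all(point_in_intervals(out_probes$chrom, out_probes$pos, mem)))
})

test_that("expression classes split RPKM >= 1 genes into near-equal quartiles", {
  genes <- make_genes(sprintf("g%d", 1:6), "chr1",
                      seq(0L, 5000L, by = 1000L),
                      seq(500L, 5500L, by = 1000L), "+",
                      rpkm = c(0, 0.5, 1, 2, 4, 8))
  cls <- classify_gene_activity(genes)
  expect_equal(cls$class, c("NA", "NA", "Q1", "Q2", "Q3", "Q4"))

  genes$rpkm <- c(0.999, 1, 1, 1, 1, 1)
  cls2 <- classify_gene_activity(genes)
  expect_equal(cls2$class[1L], "NA")
  sizes <- table(cls2$class[-1L])
  expect_lte(diff(range(sizes)), 1L)
  # stable tie order: equal values classed in input order
  expect_equal(cls2$class[-1L], sort(cls2$class[-1L]))

  genes$rpkm <- rep(0.2, 6L)
  expect_warning(cls3 <- classify_gene_activity(genes), "RPKM")
  expect_true(all(cls3$class == "NA"))
  genes$rpkm[1L] <- NA
  expect_error(classify_gene_activity(genes), "rpkm")
})
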