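test_that("motif scanning honours IUPAC codes, strands and panels", {
  g <- tiny_genome(chr1 = "ACATGG")
  idx <- scan_recognition_sites(g, restriction_motifs("NlaIII"))
  expect_equal(idx$chr1, 1L)

  g2 <- tiny_genome(chr1 = "TTAATTAA")
  expect_equal(scan_recognition_sites(g2, restriction_motifs("MseI"))$chr1,
               c(0L, 4L))

  g3 <- tiny_genome(chr1 = "AAGATTCAA")  # GANTC matches GATTC
  expect_equal(scan_recognition_sites(g3, restriction_motifs("HinfI"))$chr1,
               2L)

  # non-palindromic motif: minus-strand occurrence reported in forward
  # coordinates (CCTAG at 1 is the reverse complement of CTAGG)
  motifs <- restriction_motifs(data.frame(enzyme_name = "toy",
                                          motif = "CTAGG"))
  g4 <- tiny_genome(chr1 = "ACCTAGAACTAGG")
  expect_equal(scan_recognition_sites(g4, motifs)$chr1, c(1L, 8L))

  # panel union is deduplicated and sorted
  g5 <- tiny_genome(chr1 = "TTAACATGTTAA")
  idx5 <- scan_recognition_sites(g5, restriction_motifs(c("NlaIII",
                                                          "MseI")))
  expect_equal(idx5$chr1, c(0L, 4L, 8L))

  expect_error(restriction_motifs(data.frame(enzyme_name = "bad",
                                             motif = "CAT")), ">= 4")
  expect_error(restriction_motifs(data.frame(enzyme_name = "bad",
                                             motif = "CAFG")), "IUPAC")
})

test_that("distance to the nearest recognition site is a plain gap", {
  expect_equal(distance_to_nearest_site(100L, c(90L, 120L)), 10L)
  expect_equal(distance_to_nearest_site(90L, c(90L, 120L)), 0L)
  expect_equal(distance_to_nearest_site(5L, 5L), 0L)
  expect_equal(distance_to_nearest_site(c(0L, 200L), c(90L, 120L)),
               c(90L, 80L))
  expect_error(distance_to_nearest_site(5L, integer(0)), "no recognition")
})

test_that("the uniqueness filter agrees with a sliding-window identity scan", {
  set.seed(71)
  g <- simulate_genome(1L, 10000L, seed = 71L)
  s <- as.character(g[[1L]])
  # plant an exact duplicate of a 40 bp fragment
  dup <- substr(s, 501, 540)
  s2 <- paste0(substr(s, 1, 7000), dup, substr(s, 7041, 10000))
  gd <- tiny_genome(chr1 = s2)
  expect_false(is_uniquely_mappable("chr1", 500L, 540L, gd, 0.98))
  expect_true(is_uniquely_mappable("chr1", 500L, 540L, g, 0.98))
  # fragments below 20 bp are not analyzable
  expect_false(is_uniquely_mappable("chr1", 500L, 518L, g, 0.98))

  # a 99%-identical second copy of a 100 bp fragment fails at 0.98 but
  # passes at 0.995
  frag <- substr(s, 1001, 1100)
  near <- frag
  substr(near, 50, 50) <- chartr("ACGT", "GTAC", substr(near, 50, 50))
  gn <- tiny_genome(chr1 = paste0(substr(s, 1, 8000), near,
                                  substr(s, 8101, 10000)))
  expect_false(is_uniquely_mappable("chr1", 1000L, 1100L, gn, 0.98))
  expect_true(is_uniquely_mappable("chr1", 1000L, 1100L, gn, 0.995))

  # oracle agreement on a tiny genome across random fragments
  gt <- simulate_genome(1L, 10000L, seed = 72L)
  for (start in c(100L, 2050L, 9000L)) {
    for (len in c(20L, 35L)) {
      frag <- substr(as.character(gt[[1L]]), start + 1L, start + len)
      expect_equal(
        is_uniquely_mappable("chr1", start, start + len, gt, 0.98),
        bf_count_occurrences(frag, gt, 0.98) == 1L,
        info = paste("start", start, "len", len))
    }
  }
})

test_that("umMRCs match the parent restriction-site distance exactly", {
  fx <- study_fixture()
  sites <- simulate_integrations(fx$annotation, integration_bias("mlv_like"),
                                 12L, "MLV", seed = 81L)
  params <- control_params(n_candidates_um = 12L)
  um <- generate_ummrc(sites, fx$index, fx$genome, params, seed = 82L)
  expect_equal(nrow(um), 12L * 3L)
  d_parent <- vapply(seq_len(nrow(sites)), function(i) {
    distance_to_nearest_site(sites$pos[i], fx$index[[sites$chrom[i]]])
  }, integer(1L))
  names(d_parent) <- sites$site_id
  d_ctrl <- vapply(seq_len(nrow(um)), function(i) {
    distance_to_nearest_site(um$pos[i], fx$index[[um$chrom[i]]])
  }, integer(1L))
  expect_equal(d_ctrl, unname(d_parent[um$parent_site_id]))
  expect_equal(um$dist_to_site, unname(d_parent[um$parent_site_id]))

  # reproducible and invariant to input site ordering
  um2 <- generate_ummrc(sites, fx$index, fx$genome, params, seed = 82L)
  expect_identical(um, um2)
  perm <- sites[rev(seq_len(nrow(sites))), , drop = FALSE]
  um3 <- generate_ummrc(perm, fx$index, fx$genome, params, seed = 82L)
  expect_identical(um, um3)
})

test_that("control generation fails loudly when matching is impossible", {
  motifs <- restriction_motifs(data.frame(enzyme_name = "toy",
                                          motif = "AAAAAA"))
  g2 <- tiny_genome(chr1 = paste0(strrep("CGCT", 250), "AAAAAA",
                                  strrep("GTCA", 250)))
  idx <- scan_recognition_sites(g2, motifs)
  expect_length(idx$chr1, 1L)
  # parent distance exceeds what a single recognition site can offer
  sites <- make_sites("chr1", 1L)
  expect_error(
    generate_ummrc(sites, idx, g2,
                   control_params(n_candidates_um = 5L,
                                  max_attempts = 200L), seed = 1L),
    "matched candidates")
})

test_that("agMRC selection is rank-optimal against a brute-force oracle", {
  fx <- study_fixture()
  ann <- fx$annotation
  act <- ann$genes[ann$genes$active, , drop = FALSE]
  sites <- simulate_integrations(ann, integration_bias("hiv_like"), 8L,
                                 "HIV", seed = 91L)
  params <- control_params(n_candidates_um = 10L, n_candidates_ag = 25L)
  ag <- generate_agmrc(sites, act, fx$genome, fx$index, params, seed = 92L,
                       keep_candidates = TRUE)
  expect_true(all(!is.na(ag$dist_to_active_gene)))
  d_site <- point_interval_distance(sites$chrom, sites$pos,
                                    act[c("chrom", "start", "end")])
  names(d_site) <- sites$site_id
  pools <- attr(ag, "candidates")
  for (sid in sites$site_id) {
    sel <- ag[ag$parent_site_id == sid, , drop = FALSE]
    pool <- pools[[sid]]
    sel_delta <- abs(sel$dist_to_active_gene - d_site[[sid]])
    # oracle: sort all candidate deltas; the selected multiset of deltas
    # must equal the 3 smallest
    expect_equal(sort(sel_delta), sort(pool$abs_delta)[1:3],
                 info = sid)
    worst <- max(sel_delta)
    unsel <- pool$abs_delta[!(paste0(pool$chrom, ":", pool$pos) %in%
                                paste0(sel$chrom, ":", sel$pos))]
    expect_true(all(unsel >= worst - 1e-9), info = sid)
  }
  # sites inside an active gene with enough d=0 candidates get d=0 controls
  inside <- which(d_site == 0)
  if (length(inside) > 0L) {
    for (sid in sites$site_id[inside]) {
      pool <- pools[[sid]]
      if (sum(pool$dist_to_active_gene == 0) >= 3L) {
        expect_true(all(ag$dist_to_active_gene[
          ag$parent_site_id == sid] == 0))
      }
    }
  }
  expect_error(generate_agmrc(sites, act[0, ], fx$genome, fx$index,
                              params, seed = 1L), "no active genes")
})

test_that("agMRC tie-breaking is random but rank-invariant", {
  # four candidate distances {0, 5, 10, 100}, site distance 7:
  # |delta| = {7, 2, 3, 93} -> selected distances {5, 10, 0}
  delta <- abs(c(0, 5, 10, 100) - 7)
  expect_equal(sort(c(0, 5, 10, 100)[order(delta)][1:3]), c(0, 5, 10))
  # enumerate both resolutions of a tie at the selection boundary: the
  # chosen |delta| multiset is invariant
  cand <- c(1, 4, 6, 6, 50)
  site_d <- 0
  sets <- replicate(20, {
    sel <- order(abs(cand - site_d), runif(length(cand)))[1:3]
    sort(abs(cand[sel] - site_d))
  })
  expect_true(all(apply(sets, 2, identical, y = c(1, 4, 6))))
})
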