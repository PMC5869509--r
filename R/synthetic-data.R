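#' Simulate a toy multi-chromosome genome
#'
#' Draws i.i.d. bases with the requested GC content. The result is a
#' [Biostrings::DNAStringSet] named `chr1..chrN`, the genome container used
#' throughout the package.
#'
#' @param n_chroms Number of chromosomes (>= 1).
#' @param chrom_length Length of each chromosome in bp (>= 10000).
#' @param gc_content Target GC fraction in (0, 1). Default 0.41, the
#'   approximate GC content of the human genome.
#' @param seed Integer seed; the result is bit-reproducible for a fixed seed.
#' @return Named `DNAStringSet`.
#' @examples
#' g <- simulate_genome(2, 10000, seed = 1)
#' names(g)
#' @export
simulate_genome <- function(n_chroms = 3L, chrom_length = 100000L,
                            gc_content = 0.41, seed = NULL) {
  stopifnot(n_chroms >= 1L, chrom_length >= 10000L,
            gc_content > 0, gc_content < 1)
  p <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
         G = gc_content / 2, T = (1 - gc_content) / 2)
  seqs <- with_seed(seed, {
    vapply(seq_len(n_chroms), function(i) {
      paste(sample(names(p), chrom_length, replace = TRUE, prob = p),
            collapse = "")
    }, character(1L))
  })
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- paste0("chr", seq_len(n_chroms))
  out
}

#' Parameters for the synthetic annotation
#'
#' Defaults describe the study conditions the rest of the package is
#' exercised under: a sparse gene complement (about 12% of the genome in
#' gene bodies, half of the genes active) so that random positions are
#' typically far from a TSS while gene-body integrations are close, as in a
#' mammalian genome shrunk to desk scale.
#'
#' @param n_genes Total genes to place (spread across chromosomes).
#' @param gene_length_range Gene body length range in bp (uniform draw).
#' @param active_fraction Fraction of genes that are transcriptionally
#'   active.
#' @param h3k4me3_width Width of the H3K4me3 peak centred on each active TSS.
#' @param tss_segment_width Width of the `Tss` chromatin segment centred on
#'   each active TSS.
#' @param cage_peak_width Width of the CAGE peak centred on each active TSS;
#'   odd by default so the peak midpoint falls exactly on the TSS base.
#' @param n_enhancers Enhancer (`Enh`) segments to place, split between
#'   intragenic and intergenic locations.
#' @param enhancer_width Enhancer segment width in bp.
#' @param rpkm_meanlog,rpkm_sdlog Log-normal parameters for active-gene RPKM
#'   (inactive genes get RPKM 0).
#' @param decouple_criteria If `TRUE`, one third of the active genes keep
#'   only their CAGE evidence (no H3K4me3 peak or Tss segment), so the three
#'   active-gene criteria disagree for those genes.
#' @return A named list of parameters for [simulate_annotation()].
#' @export
annotation_params <- function(n_genes = 12L,
                              gene_length_range = c(2000L, 4000L),
                              active_fraction = 0.5,
                              h3k4me3_width = 1000L,
                              tss_segment_width = 800L,
                              cage_peak_width = 31L,
                              n_enhancers = 9L,
                              enhancer_width = 500L,
                              rpkm_meanlog = 2,
                              rpkm_sdlog = 1,
                              decouple_criteria = FALSE) {
  stopifnot(n_genes >= 1L, length(gene_length_range) == 2L,
            gene_length_range[1L] <= gene_length_range[2L],
            active_fraction >= 0, active_fraction <= 1)
  as.list(environment())
}

#' Simulate genes, chromatin segments, peak tracks and expression
#'
#' Places non-overlapping genes on the genome, marks a fraction as active
#' (stratified so that, budget permitting, every chromosome with genes
#' carries at least one active gene — otherwise sites on that chromosome
#' could not be matched on active-gene distance) and builds the evidence
#' tracks the analysis consumes. By construction,
#' every active gene's TSS sits at the centre of an H3K4me3 peak, a `Tss`
#' chromatin segment and a CAGE peak (midpoint on the TSS base), so the
#' three active-gene criteria agree unless `decouple_criteria` is set.
#' `Enh` segments are placed both inside gene bodies and intergenically;
#' `Elon` segments cover the interior of active gene bodies and `Quies`
#' segments fill a sample of the remaining gaps, giving the segment track
#' non-trivial Active and Regulatory groups. Active genes draw a log-normal
#' RPKM, inactive genes get 0.
#'
#' @param genome `DNAStringSet` from [simulate_genome()].
#' @param params List from [annotation_params()].
#' @param seed Integer seed.
#' @return An object of class `provsel_annotation`: a list with `genes`,
#'   `segments`, `peaks` (named list of peak tracks, at least `H3K4me3`),
#'   `cage`, and `chrom_lengths`.
#' @export
simulate_annotation <- function(genome, params = annotation_params(),
                                seed = NULL) {
  chrom_lengths <- stats::setNames(Biostrings::width(genome), names(genome))
  with_seed(seed, {
    genes <- place_genes(chrom_lengths, params)
    active <- rep(FALSE, nrow(genes))
    n_active <- round(params$active_fraction * nrow(genes))
    if (n_active > 0L) {
      # stratified: every chromosome with genes keeps an active gene when
      # the budget allows, so no chromosome is unmatchable on
      # active-gene distance
      reps <- vapply(split(seq_len(nrow(genes)), genes$chrom),
                     function(ix) ix[sample.int(length(ix), 1L)],
                     integer(1L))
      if (length(reps) >= n_active) {
        sel <- sample(reps, n_active)
      } else {
        rest <- setdiff(seq_len(nrow(genes)), reps)
        sel <- c(reps, sample(rest)[seq_len(n_active - length(reps))])
      }
      active[sel] <- TRUE
    }
    genes$rpkm <- ifelse(active,
                         stats::rlnorm(nrow(genes), params$rpkm_meanlog,
                                       params$rpkm_sdlog),
                         0)
    genes$active <- active

    cage_only <- rep(FALSE, nrow(genes))
    if (params$decouple_criteria && n_active > 0L) {
      act_idx <- which(active)
      cage_only[sample(act_idx, max(1L, length(act_idx) %/% 3L))] <- TRUE
    }

    tss_track <- function(width, idx) {
      half <- width %/% 2L
      data.frame(chrom = genes$chrom[idx],
                 start = pmax(genes$tss[idx] - half, 0L),
                 end = pmin(genes$tss[idx] - half + width,
                            chrom_lengths[genes$chrom[idx]]),
                 stringsAsFactors = FALSE)
    }
    evid_idx <- which(active & !cage_only)
    cage_idx <- which(active)

    peaks_h3k4me3 <- tss_track(params$h3k4me3_width, evid_idx)
    tss_seg <- tss_track(params$tss_segment_width, evid_idx)
    cage <- tss_track(params$cage_peak_width, cage_idx)

    segments <- build_segments(genes, tss_seg, params, chrom_lengths)

    peaks <- list(H3K4me3 = peak_track(peaks_h3k4me3, "H3K4me3"))
    enh <- segments[segments$state == "Enh", c("chrom", "start", "end")]
    if (nrow(enh) > 0L) {
      peaks$H3K4me1 <- peak_track(enh, "H3K4me1")
      peaks$H3K27ac <- peak_track(rbind(enh, peaks_h3k4me3), "H3K27ac")
    }
    cage <- if (nrow(cage) > 0L) {
      cage <- merge_intervals(cage, bookended = FALSE)
      cage$mark <- "CAGE"
      cage
    } else {
      data.frame(chrom = character(), start = integer(), end = integer(),
                 mark = character(), stringsAsFactors = FALSE)
    }

    structure(list(genes = genes, segments = segments, peaks = peaks,
                   cage = cage, chrom_lengths = chrom_lengths),
              class = "provsel_annotation")
  })
}

peak_track <- function(df, mark) {
  if (nrow(df) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), mark = character(),
                      stringsAsFactors = FALSE))
  }
  out <- merge_intervals(df, bookended = FALSE)
  out$mark <- mark
  out
}

# Non-overlapping gene placement: genes are distributed over chromosomes
# proportionally to length, each chromosome is cut into equal slots and one
# gene is placed uniformly inside its slot. Guarantees disjoint genes with
# realistic spread; errors when a slot cannot hold the longest gene.
place_genes <- function(chrom_lengths, params) {
  n <- params$n_genes
  w <- chrom_lengths / sum(chrom_lengths)
  per_chrom <- diff(round(cumsum(c(0, w)) * n))
  names(per_chrom) <- names(chrom_lengths)
  rows <- list()
  gi <- 0L
  for (ch in names(chrom_lengths)) {
    k <- per_chrom[[ch]]
    if (k == 0L) next
    slot <- chrom_lengths[[ch]] %/% k
    if (slot < params$gene_length_range[2L] + 2L) {
      stop_bad("genome too small for ", n, " genes of length up to ",
               params$gene_length_range[2L])
    }
    for (j in seq_len(k)) {
      gi <- gi + 1L
      len <- sample(params$gene_length_range[1L]:params$gene_length_range[2L],
                    1L)
      lo <- (j - 1L) * slot
      start <- lo + sample.int(slot - len, 1L)
      rows[[gi]] <- data.frame(
        gene_id = sprintf("g%03d", gi), chrom = ch,
        start = start, end = start + len,
        strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
    }
  }
  genes <- validate_genes(do.call(rbind, rows))
  genes
}

# Assemble the chromatin segment track: Tss segments at active TSSs, Elon in
# active gene interiors, Enh intra- and intergenic, Quies filling sampled
# gaps. Overlaps against already placed segments are dropped so the track
# stays disjoint (Tss has priority).
build_segments <- function(genes, tss_seg, params, chrom_lengths) {
  segs <- if (nrow(tss_seg) > 0L) {
    cbind(merge_intervals(tss_seg, bookended = FALSE), state = "Tss")
  } else {
    data.frame(chrom = character(), start = integer(), end = integer(),
               state = character(), stringsAsFactors = FALSE)
  }
  add_if_free <- function(segs, cand, state) {
    for (i in seq_len(nrow(cand))) {      # sequential: batch stays disjoint
      clash <- any(segs$chrom == cand$chrom[i] &
                     segs$start < cand$end[i] & cand$start[i] < segs$end)
      if (!clash) {
        segs <- rbind(segs, data.frame(chrom = cand$chrom[i],
                                       start = cand$start[i],
                                       end = cand$end[i], state = state,
                                       stringsAsFactors = FALSE))
      }
    }
    segs
  }

  act <- genes[genes$active, , drop = FALSE]
  if (nrow(act) > 0L) {
    mid <- (act$start + act$end) %/% 2L
    elon <- data.frame(chrom = act$chrom, start = mid,
                       end = pmin(mid + 600L, act$end),
                       stringsAsFactors = FALSE)
    elon <- elon[elon$start < elon$end, , drop = FALSE]
    segs <- add_if_free(segs, elon, "Elon")
  }

  n_enh <- params$n_enhancers
  if (n_enh > 0L) {
    half_intra <- n_enh %/% 2L
    cand <- list()
    if (nrow(act) > 0L && half_intra > 0L) {
      pick <- sample.int(nrow(act), half_intra, replace = TRUE)
      off <- vapply(pick, function(i) {
        sample.int(max(act$end[i] - act$start[i] - params$enhancer_width, 1L),
                   1L)
      }, integer(1L))
      cand[[1L]] <- data.frame(chrom = act$chrom[pick],
                               start = act$start[pick] + off,
                               end = act$start[pick] + off +
                                 params$enhancer_width,
                               stringsAsFactors = FALSE)
    }
    ch <- sample(names(chrom_lengths), n_enh - half_intra, replace = TRUE)
    st <- vapply(ch, function(c2) {
      sample.int(chrom_lengths[[c2]] - params$enhancer_width, 1L)
    }, integer(1L))
    cand[[2L]] <- data.frame(chrom = ch, start = st,
                             end = st + params$enhancer_width,
                             stringsAsFactors = FALSE)
    cand <- do.call(rbind, cand)
    cand$end <- pmin(cand$end, chrom_lengths[cand$chrom])
    cand <- cand[cand$start < cand$end & cand$start >= 0L, , drop = FALSE]
    segs <- add_if_free(segs, cand, "Enh")
  }

  # Quies background in a sample of intergenic gaps
  for (ch in names(chrom_lengths)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    bounds <- sort(c(0L, g$start, g$end, chrom_lengths[[ch]]))
    gaps <- data.frame(chrom = ch, start = bounds[-length(bounds)],
                       end = bounds[-1L], stringsAsFactors = FALSE)
    gaps <- gaps[(gaps$end - gaps$start) > 3000L, , drop = FALSE]
    if (nrow(gaps) == 0L) next
    gaps$start <- gaps$start + 1000L
    gaps$end <- gaps$end - 1000L
    segs <- add_if_free(segs, gaps[gaps$start < gaps$end, , drop = FALSE],
                        "Quies")
  }
  sort_intervals(segs)
}

#' Integration bias model
#'
#' A multinomial mixture over four mutually exclusive placement components:
#' inside an active gene body (uniform over the body), TSS-proximal (signed
#' offset from an active TSS drawn from a two-sided exponential),
#' enhancer-proximal (two-sided exponential offset from an `Enh` segment
#' midpoint) and uniform background. `p_sense` is the probability that an
#' intragenic provirus lands in sense orientation relative to its host gene;
#' all other sites get a uniform strand.
#'
#' Presets mirror the targeting profiles of the three vector classes as
#' realized by cohorts of long-term stably expressed proviruses:
#' `"hiv_like"` (strong active-gene-body preference), `"mlv_like"`
#' (TSS- and enhancer-proximal, antisense-leaning) and `"aslv_like"`
#' (random-like with a weak gene preference; the TSS-proximal mass of 0.115
#' matches the fraction of clones that escape silencing).
#'
#' @param preset Optional preset name; explicit arguments override nothing —
#'   either give a preset or the individual probabilities.
#' @param p_in_gene,p_near_tss,p_near_enhancer Component probabilities; must
#'   sum to at most 1 (remainder is uniform background).
#' @param tss_distance_scale,enhancer_distance_scale Exponential scales (bp)
#'   of the two-sided offset draws.
#' @param p_sense Sense-orientation probability for intragenic sites.
#' @return A list of class `provsel_bias`.
#' @examples
#' integration_bias("hiv_like")
#' @export
integration_bias <- function(preset = NULL, p_in_gene = 0, p_near_tss = 0,
                             p_near_enhancer = 0,
                             tss_distance_scale = 1000,
                             enhancer_distance_scale = 500,
                             p_sense = 0.5) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("aslv_like", "hiv_like", "mlv_like"))
    return(switch(preset,
      aslv_like = integration_bias(NULL, p_in_gene = 0.10, p_near_tss = 0.115,
                                   p_near_enhancer = 0,
                                   tss_distance_scale = 1000,
                                   p_sense = 0.75),
      hiv_like = integration_bias(NULL, p_in_gene = 0.80, p_near_tss = 0.02,
                                  p_near_enhancer = 0,
                                  tss_distance_scale = 10000,
                                  p_sense = 0.5),
      mlv_like = integration_bias(NULL, p_in_gene = 0.10, p_near_tss = 0.45,
                                  p_near_enhancer = 0.25,
                                  tss_distance_scale = 1000,
                                  enhancer_distance_scale = 500,
                                  p_sense = 0.25)))
  }
  probs <- c(p_in_gene, p_near_tss, p_near_enhancer)
  stopifnot(all(probs >= 0), all(probs <= 1), sum(probs) <= 1,
            p_sense >= 0, p_sense <= 1,
            tss_distance_scale > 0, enhancer_distance_scale > 0)
  structure(list(p_in_gene = p_in_gene, p_near_tss = p_near_tss,
                 p_near_enhancer = p_near_enhancer,
                 tss_distance_scale = tss_distance_scale,
                 enhancer_distance_scale = enhancer_distance_scale,
                 p_sense = p_sense),
            class = "provsel_bias")
}

#' Simulate an integration-site cohort
#'
#' Draws `n` integration sites from the mixture defined by `bias` over the
#' tracks in `annotation`. Each site records the mixture `component` that
#' generated it (`in_gene`, `near_tss`, `near_enhancer`, `background`),
#' which downstream clone simulation maps to a silencing feature class.
#'
#' @param annotation `provsel_annotation` from [simulate_annotation()].
#' @param bias `provsel_bias` from [integration_bias()].
#' @param n Number of sites (>= 1).
#' @param vector Vector group label for the cohort.
#' @param seed Integer seed.
#' @param site_prefix Prefix for generated `site_id`/`clone_id` values.
#' @return Site data.frame (`site_id`, `chrom`, `pos`, `strand`, `vector`,
#'   `clone_id`, `component`).
#' @export
simulate_integrations <- function(annotation, bias, n, vector = "other",
                                  seed = NULL, site_prefix = "s") {
  stopifnot(inherits(annotation, "provsel_annotation"),
            inherits(bias, "provsel_bias"), n >= 1L,
            vector %in% VECTOR_GROUPS)
  genes <- annotation$genes
  act <- genes[genes$active, , drop = FALSE]
  if (nrow(act) == 0L && (bias$p_in_gene > 0 || bias$p_near_tss > 0)) {
    stop_bad("annotation has no active genes but bias places mass on them")
  }
  enh <- annotation$segments[annotation$segments$state == "Enh", ,
                             drop = FALSE]
  if (nrow(enh) == 0L && bias$p_near_enhancer > 0) {
    stop_bad("annotation has no Enh segments but p_near_enhancer > 0")
  }
  lens <- annotation$chrom_lengths
  with_seed(seed, {
    comp <- sample(c("in_gene", "near_tss", "near_enhancer", "background"),
                   n, replace = TRUE,
                   prob = c(bias$p_in_gene, bias$p_near_tss,
                            bias$p_near_enhancer,
                            1 - bias$p_in_gene - bias$p_near_tss -
                              bias$p_near_enhancer))
    chrom <- character(n); pos <- integer(n); strand <- character(n)
    for (i in seq_len(n)) {
      if (comp[i] == "in_gene") {
        g <- sample.int(nrow(act), 1L,
                        prob = act$end - act$start)  # bp-uniform over bodies
        chrom[i] <- act$chrom[g]
        pos[i] <- act$start[g] + sample.int(act$end[g] - act$start[g], 1L) - 1L
        sense <- stats::runif(1L) < bias$p_sense
        strand[i] <- if (sense) act$strand[g] else setdiff(c("+", "-"),
                                                           act$strand[g])
      } else if (comp[i] == "near_tss") {
        g <- sample.int(nrow(act), 1L)
        off <- round(stats::rexp(1L, 1 / bias$tss_distance_scale)) *
          sample(c(-1L, 1L), 1L)
        chrom[i] <- act$chrom[g]
        pos[i] <- clamp(act$tss[g] + off, 0L, lens[[chrom[i]]] - 1L)
        strand[i] <- sample(c("+", "-"), 1L)
      } else if (comp[i] == "near_enhancer") {
        e <- sample.int(nrow(enh), 1L)
        off <- round(stats::rexp(1L, 1 / bias$enhancer_distance_scale)) *
          sample(c(-1L, 1L), 1L)
        chrom[i] <- enh$chrom[e]
        mid <- (enh$start[e] + enh$end[e]) %/% 2L
        pos[i] <- clamp(mid + off, 0L, lens[[chrom[i]]] - 1L)
        strand[i] <- sample(c("+", "-"), 1L)
      } else {
        chrom[i] <- sample(names(lens), 1L, prob = lens)
        pos[i] <- sample.int(lens[[chrom[i]]], 1L) - 1L
        strand[i] <- sample(c("+", "-"), 1L)
      }
    }
    ids <- sprintf("%s%04d", site_prefix, seq_len(n))
    validate_sites(data.frame(
      site_id = ids, chrom = chrom, pos = pos, strand = strand,
      vector = vector, clone_id = sub("^", "c", ids),
      component = comp, stringsAsFactors = FALSE))
  })
}

clamp <- function(x, lo, hi) as.integer(pmin(pmax(x, lo), hi))

#' Silencing model for clone trajectories
#'
#' Per-clone %GFP+ follows deterministic exponential decay,
#' `100 * exp(-lambda_class * t)`, with class-specific rate `lambda` (per
#' day), plus Gaussian measurement noise, clipped to \[0, 100\]. The class of
#' a clone is the feature class of its integration site.
#'
#' Presets encode the silencing regimes of the three vector classes:
#' `"aslv_like"` (TSS-proximal proviruses fully protected, everything else
#' silenced fast), `"hiv_like"` (slow decay tuned so that gene-body clones
#' sit near the 90% stability threshold at 60 dpi) and `"mlv_like"`
#' (negligible decay everywhere).
#'
#' @param preset Optional preset name.
#' @param lambda_by_class Named non-negative rates per day for classes
#'   `near_active_tss`, `near_enhancer`, `gene_body`, `background`.
#' @param measurement_noise_sd Gaussian noise SD in percentage points.
#' @return A list of class `provsel_silencing`.
#' @export
silencing_model <- function(preset = NULL,
                            lambda_by_class = c(near_active_tss = 0,
                                                near_enhancer = 0,
                                                gene_body = 0,
                                                background = 0),
                            measurement_noise_sd = 0) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("aslv_like", "hiv_like", "mlv_like"))
    return(switch(preset,
      aslv_like = silencing_model(NULL,
        lambda_by_class = c(near_active_tss = 0, near_enhancer = 0.02,
                            gene_body = 0.08, background = 0.08),
        measurement_noise_sd = 2),
      hiv_like = silencing_model(NULL,
        lambda_by_class = c(near_active_tss = 0, near_enhancer = 0.001,
                            gene_body = -log(0.9) / 60,
                            background = 0.03),
        measurement_noise_sd = 2),
      mlv_like = silencing_model(NULL,
        lambda_by_class = c(near_active_tss = 0.0005, near_enhancer = 0.0005,
                            gene_body = 0.0005, background = 0.01),
        measurement_noise_sd = 2)))
  }
  stopifnot(all(lambda_by_class >= 0), measurement_noise_sd >= 0,
            !is.null(names(lambda_by_class)))
  structure(list(lambda_by_class = lambda_by_class,
                 measurement_noise_sd = measurement_noise_sd),
            class = "provsel_silencing")
}

#' Map generator components to silencing feature classes
#'
#' Sites produced by [simulate_integrations()] carry the mixture component
#' that placed them; this maps it onto the silencing classes used by
#' [silencing_model()]. For sites without a `component` column (e.g. loaded
#' from file), use [classify_site_context()] instead.
#'
#' @param sites Site data.frame with a `component` column.
#' @return Character vector of feature classes.
#' @export
site_feature_class <- function(sites) {
  if (is.null(sites$component)) {
    stop_bad("sites have no component column; use classify_site_context()")
  }
  map <- c(in_gene = "gene_body", near_tss = "near_active_tss",
           near_enhancer = "near_enhancer", background = "background")
  unname(map[sites$component])
}

#' Classify sites by annotation context
#'
#' Geometric feature-class assignment for sites of unknown provenance:
#' `near_active_tss` within `tss_window` bp of an active TSS, else
#' `gene_body` when inside any gene body, else `near_enhancer` within
#' `enhancer_window` bp of an `Enh` segment, else `background`.
#'
#' @param sites Site data.frame.
#' @param annotation `provsel_annotation`.
#' @param tss_window,enhancer_window Windows in bp.
#' @return Character vector of feature classes.
#' @export
classify_site_context <- function(sites, annotation, tss_window = 2000L,
                                  enhancer_window = 1000L) {
  act <- annotation$genes[annotation$genes$active, , drop = FALSE]
  cls <- rep("background", nrow(sites))
  if (nrow(act) > 0L) {
    tssd <- point_interval_distance(sites$chrom, sites$pos,
                                    data.frame(chrom = act$chrom,
                                               start = act$tss,
                                               end = act$tss + 1L))
    cls[!is.na(tssd) & tssd <= tss_window] <- "near_active_tss"
  }
  ing <- point_in_intervals(sites$chrom, sites$pos, annotation$genes)
  cls[cls == "background" & ing] <- "gene_body"
  enh <- annotation$segments[annotation$segments$state == "Enh", ,
                             drop = FALSE]
  if (nrow(enh) > 0L) {
    ed <- point_interval_distance(sites$chrom, sites$pos, enh)
    cls[cls == "background" & !is.na(ed) & ed <= enhancer_window] <-
      "near_enhancer"
  }
  cls
}

#' Simulate clone GFP trajectories
#'
#' One clone per integration site. %GFP+ at each timepoint is
#' `clip(100 * exp(-lambda * t) + noise, 0, 100)` with the class-specific
#' rate from `model` and i.i.d. Gaussian measurement noise.
#'
#' @param sites Site data.frame; feature classes are taken from `classes`.
#' @param model `provsel_silencing` from [silencing_model()].
#' @param timepoints Integer dpi vector (strictly positive).
#' @param seed Integer seed.
#' @param classes Feature class per site; defaults to
#'   [site_feature_class()] of `sites`.
#' @return Clone data.frame (`clone_id`, `vector`, one `dpi<N>` column per
#'   timepoint).
#' @export
simulate_clones <- function(sites, model, timepoints = c(30L, 60L),
                            seed = NULL, classes = site_feature_class(sites)) {
  stopifnot(inherits(model, "provsel_silencing"), all(timepoints > 0L),
            length(classes) == nrow(sites))
  unknown <- setdiff(unique(classes), names(model$lambda_by_class))
  if (length(unknown) > 0L) {
    stop_bad("no silencing rate for feature class: ",
             paste(unknown, collapse = ", "))
  }
  lam <- model$lambda_by_class[classes]
  out <- data.frame(clone_id = sites$clone_id, vector = sites$vector,
                    stringsAsFactors = FALSE)
  with_seed(seed, {
    for (t in sort(as.integer(timepoints))) {
      v <- 100 * exp(-lam * t)
      if (model$measurement_noise_sd > 0) {
        v <- v + stats::rnorm(length(v), 0, model$measurement_noise_sd)
      }
      out[[paste0("dpi", t)]] <- pmin(pmax(v, 0), 100)
    }
    validate_clones(out)
  })
}

#' Write all synthetic tracks to a directory
#'
#' Emits the genome as FASTA plus every annotation track and cohort table in
#' the package's standard text formats, so a simulated study can be consumed
#' by the file-based entry points.
#'
#' @param genome `DNAStringSet`.
#' @param annotation `provsel_annotation`.
#' @param dir Output directory (created if needed).
#' @param sites,clones Optional cohort tables to include.
#' @return `dir`, invisibly.
#' @export
write_synthetic_data <- function(genome, annotation, dir,
                                 sites = NULL, clones = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(genome, file.path(dir, "genome.fa"))
  write_gene_table(annotation$genes, file.path(dir, "genes.tsv"))
  write_intervals(annotation$segments, file.path(dir, "segments.bed"))
  for (mk in names(annotation$peaks)) {
    write_intervals(annotation$peaks[[mk]],
                    file.path(dir, paste0("peaks_", mk, ".bed")))
  }
  write_intervals(annotation$cage, file.path(dir, "cage.bed"))
  if (!is.null(sites)) write_sites(sites, file.path(dir, "sites.tsv"))
  if (!is.null(clones)) write_clone_table(clones, file.path(dir, "clones.csv"))
  invisible(dir)
}
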