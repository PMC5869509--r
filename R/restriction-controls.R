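#' Restriction enzyme recognition motifs
#'
#' Returns the recognition motifs for a panel of enzymes, either from the
#' built-in table (the enzymes used for junction amplification: NlaIII,
#' MseI and the SpeI/NheI/XbaI mix, plus a few common extras) or from a
#' custom data.frame. Motifs are IUPAC DNA strings of length >= 4.
#'
#' @param enzymes Character vector of enzyme names, or a data.frame with
#'   columns `enzyme_name` and `motif`.
#' @return data.frame with columns `enzyme_name`, `motif`.
#' @examples
#' restriction_motifs(c("NlaIII", "MseI"))
#' @export
restriction_motifs <- function(enzymes = c("NlaIII", "MseI")) {
  builtin <- data.frame(
    enzyme_name = c("NlaIII", "MseI", "SpeI", "NheI", "XbaI", "DpnII",
                    "HinfI"),
    motif = c("CATG", "TTAA", "ACTAGT", "GCTAGC", "TCTAGA", "GATC",
              "GANTC"),
    stringsAsFactors = FALSE)
  if (is.data.frame(enzymes)) {
    df <- enzymes[c("enzyme_name", "motif")]
  } else {
    miss <- setdiff(enzymes, builtin$enzyme_name)
    if (length(miss) > 0L) {
      stop_bad("unknown enzyme(s): ", paste(miss, collapse = ", "),
               "; pass a data.frame with enzyme_name and motif")
    }
    df <- builtin[match(enzymes, builtin$enzyme_name), ]
  }
  validate_motifs(df)
}

IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

validate_motifs <- function(df) {
  check_string(df$enzyme_name, "enzyme_name")
  check_string(df$motif, "motif")
  if (any(nchar(df$motif) < 4L)) stop_bad("motifs must be >= 4 bp")
  chars <- unique(unlist(strsplit(toupper(df$motif), "")))
  if (!all(chars %in% IUPAC_LETTERS)) {
    stop_bad("motif contains non-IUPAC letters")
  }
  df$motif <- toupper(df$motif)
  rownames(df) <- NULL
  df
}

#' Scan recognition sites over a genome
#'
#' Finds all occurrences of the enzyme panel's motifs. Palindromic motifs
#' (equal to their reverse complement under IUPAC) are scanned on the
#' forward strand only; non-palindromic motifs are scanned on both strands
#' with minus-strand hits reported at the forward-strand start of the
#' occurrence. The per-chromosome union over the panel is deduplicated and
#' sorted; positions are 0-based motif start coordinates.
#'
#' @param genome `DNAStringSet`.
#' @param motifs Motif data.frame from [restriction_motifs()].
#' @return Named list (one element per chromosome) of sorted integer
#'   positions, with attribute `motif_span` = the longest motif length
#'   (used to delimit junction fragments).
#' @export
scan_recognition_sites <- function(genome, motifs) {
  if (length(genome) == 0L || sum(Biostrings::width(genome)) == 0L) {
    stop_bad("empty genome")
  }
  motifs <- validate_motifs(motifs)
  out <- lapply(seq_along(genome), function(ci) {
    subject <- genome[[ci]]
    hits <- integer(0)
    for (m in motifs$motif) {
      pat <- Biostrings::DNAString(m)
      fwd <- Biostrings::start(Biostrings::matchPattern(pat, subject,
                                                        fixed = FALSE))
      hits <- c(hits, fwd)
      rc <- Biostrings::reverseComplement(pat)
      if (as.character(rc) != m) {
        rev <- Biostrings::start(Biostrings::matchPattern(rc, subject,
                                                          fixed = FALSE))
        hits <- c(hits, rev)
      }
    }
    sort(unique(hits)) - 1L
  })
  names(out) <- names(genome)
  attr(out, "motif_span") <- max(nchar(motifs$motif))
  out
}

#' Distance to the nearest recognition site
#'
#' Minimum absolute difference between a position and the recognition-site
#' start positions on its chromosome; 0 when the position coincides with a
#' site start. Errors when the chromosome has no recognition site (such a
#' position cannot be distance-matched).
#'
#' @param pos Integer position(s), 0-based.
#' @param sites Sorted integer vector of recognition-site starts on the same
#'   chromosome (one element of [scan_recognition_sites()] output).
#' @return Integer distance(s) in bp.
#' @examples
#' distance_to_nearest_site(100, c(90, 120))
#' @export
distance_to_nearest_site <- function(pos, sites) {
  point_point_distance(pos, sites)
}

#' Uniqueness filter for junction fragments
#'
#' Tests whether the fragment `[start, end)` on `chrom` has exactly one
#' full-length occurrence in the genome at identity >= `min_identity`,
#' counting both strands. Identity is ungapped: a window counts as an
#' occurrence when it has at most `L - ceiling(min_identity * L)`
#' mismatches over the full fragment length `L`. Fragments shorter than
#' 20 bp are not analyzable and return `FALSE` (candidate discarded, not an
#' error).
#'
#' @param chrom,start,end Fragment interval (0-based half-open).
#' @param genome `DNAStringSet`.
#' @param min_identity Minimum full-length identity in (0, 1].
#' @return `TRUE` iff the fragment is uniquely mappable.
#' @export
is_uniquely_mappable <- function(chrom, start, end, genome,
                                 min_identity = 0.98) {
  stopifnot(min_identity > 0, min_identity <= 1)
  len <- end - start
  if (len < 20L) return(FALSE)
  frag <- Biostrings::subseq(genome[[chrom]], start + 1L, end)
  k <- len - as.integer(ceiling(min_identity * len))
  n_hits <- sum(Biostrings::vcountPattern(frag, genome, max.mismatch = k))
  rc <- Biostrings::reverseComplement(frag)
  if (as.character(rc) != as.character(frag)) {
    n_hits <- n_hits + sum(Biostrings::vcountPattern(rc, genome,
                                                     max.mismatch = k))
  }
  n_hits == 1L
}

#' Control-generation parameters
#'
#' Defaults follow the matched-random-control protocol: 200 candidate
#' positions per integration site for umMRCs, 1000 for agMRCs, 3 controls
#' selected per site, and a 98% full-length identity uniqueness filter.
#'
#' @param n_candidates_um Candidate pool size per site for umMRC generation.
#' @param n_select Controls selected per site.
#' @param n_candidates_ag Candidate pool size per site for agMRC generation.
#' @param min_identity Uniqueness threshold, in (0, 1].
#' @param max_attempts Candidate draws allowed per site before giving up.
#' @param min_fragment Minimum junction-fragment length submitted to the
#'   uniqueness scan; shorter position-to-recognition-site spans are
#'   extended to this length.
#' @return A list of class `provsel_control_params`.
#' @export
control_params <- function(n_candidates_um = 200L, n_select = 3L,
                           n_candidates_ag = 1000L, min_identity = 0.98,
                           max_attempts = 50000L, min_fragment = 20L) {
  stopifnot(n_select >= 1L, n_select <= n_candidates_um,
            n_select <= n_candidates_ag,
            min_identity > 0, min_identity <= 1, max_attempts >= 1L,
            min_fragment >= 20L)
  structure(as.list(environment()), class = "provsel_control_params")
}

# Junction fragment for a position: spans from the position across the full
# recognition motif at the nearest site, extended (rightward, then leftward
# at chromosome ends) to min_fragment bp so the uniqueness scan always sees
# an analyzable sequence.
junction_fragment <- function(pos, site_positions, motif_span, chrom_len,
                              min_fragment) {
  s <- sort(site_positions)
  k <- findInterval(pos, s)
  cand <- c(if (k >= 1L) s[k], if (k < length(s)) s[k + 1L])
  near <- cand[which.min(abs(cand - pos))]
  lo <- min(pos, near)
  hi <- max(pos + 1L, near + motif_span)
  if (hi - lo < min_fragment) hi <- lo + min_fragment
  if (hi > chrom_len) {
    lo <- max(0L, lo - (hi - chrom_len))
    hi <- chrom_len
  }
  c(lo, hi)
}

# Candidate generator shared by umMRC and agMRC: repeatedly (a) pick a
# recognition site uniformly genome-wide, (b) offset by the parent distance
# in a uniform random direction, (c) keep the position iff it stays on the
# chromosome, its nearest-recognition-site distance equals the parent's
# exactly, and its junction fragment passes the uniqueness filter.
# Returns a data.frame of distinct candidate positions.
draw_candidates <- function(d, index, genome, chrom_lens, n_needed, params) {
  pool_chrom <- rep(names(index), lengths(index))
  pool_pos <- unlist(index, use.names = FALSE)
  motif_span <- attr(index, "motif_span")
  got_chrom <- character(n_needed); got_pos <- integer(n_needed)
  n_got <- 0L
  seen <- character(0)
  attempts <- 0L
  batch <- max(64L, 2L * n_needed)
  while (n_got < n_needed && attempts < params$max_attempts) {
    b <- min(batch, params$max_attempts - attempts)
    attempts <- attempts + b
    pick <- sample.int(length(pool_pos), b, replace = TRUE)
    dir <- sample(c(-1L, 1L), b, replace = TRUE)
    cand_chrom <- pool_chrom[pick]
    cand_pos <- pool_pos[pick] + dir * d
    ok <- cand_pos >= 0L & cand_pos < chrom_lens[cand_chrom]
    cand_chrom <- cand_chrom[ok]; cand_pos <- cand_pos[ok]
    if (length(cand_pos) == 0L) next
    for (ch in unique(cand_chrom)) {
      sel <- cand_chrom == ch
      cand_pos[sel] <- ifelse(
        point_point_distance(cand_pos[sel], index[[ch]]) == d,
        cand_pos[sel], NA_integer_)
    }
    keep <- !is.na(cand_pos)
    cand_chrom <- cand_chrom[keep]; cand_pos <- cand_pos[keep]
    if (length(cand_pos) == 0L) next
    key <- paste0(cand_chrom, ":", cand_pos)
    fresh <- !duplicated(key) & !(key %in% seen)
    cand_chrom <- cand_chrom[fresh]; cand_pos <- cand_pos[fresh]
    seen <- c(seen, key[fresh])
    for (i in seq_along(cand_pos)) {
      if (n_got >= n_needed) break
      fr <- junction_fragment(cand_pos[i], index[[cand_chrom[i]]],
                              motif_span, chrom_lens[[cand_chrom[i]]],
                              params$min_fragment)
      if (is_uniquely_mappable(cand_chrom[i], fr[1L], fr[2L], genome,
                               params$min_identity)) {
        n_got <- n_got + 1L
        got_chrom[n_got] <- cand_chrom[i]
        got_pos[n_got] <- cand_pos[i]
      }
    }
  }
  data.frame(chrom = got_chrom[seq_len(n_got)], pos = got_pos[seq_len(n_got)],
             stringsAsFactors = FALSE)
}

site_parent_distances <- function(sites, site_index) {
  vapply(seq_len(nrow(sites)), function(i) {
    idx <- site_index[[sites$chrom[i]]]
    if (is.null(idx) || length(idx) == 0L) {
      stop_bad("site ", sites$site_id[i], ": no recognition sites on ",
               sites$chrom[i])
    }
    distance_to_nearest_site(sites$pos[i], idx)
  }, integer(1L))
}

#' Generate uniquely mapped matched random controls (umMRC)
#'
#' For each integration site, builds a pool of `n_candidates_um` random
#' genomic positions whose distance to the nearest restriction-enzyme
#' recognition site equals the site's own distance *exactly*, and whose
#' junction fragment passes the uniqueness filter; `n_select` controls are
#' then drawn from the pool uniformly without replacement. Exact per-site
#' distance matching implies the matched distance distribution of the
#' protocol in its strongest form.
#'
#' Control generation is reproducible under `seed` and invariant to the
#' ordering of the input sites (per-site RNG streams are derived from the
#' sorted site ids).
#'
#' @param sites Site data.frame.
#' @param site_index Recognition-site index from [scan_recognition_sites()].
#' @param genome `DNAStringSet`.
#' @param params [control_params()].
#' @param seed Integer seed.
#' @return Control data.frame (see [read_controls()]) with kind `"umMRC"`.
#' @export
generate_ummrc <- function(sites, site_index, genome,
                           params = control_params(), seed = NULL) {
  chrom_lens <- stats::setNames(Biostrings::width(genome), names(genome))
  d_parent <- site_parent_distances(sites, site_index)
  seeds <- derive_seeds(seed, sites$site_id)
  ord <- order(sites$site_id)
  out <- lapply(ord, function(i) {
    with_seed(seeds[[sites$site_id[i]]], {
      pool <- draw_candidates(d_parent[i], site_index, genome, chrom_lens,
                              params$n_candidates_um, params)
      if (nrow(pool) < params$n_select) {
        stop_bad("site ", sites$site_id[i], ": only ", nrow(pool),
                 " matched candidates after ", params$max_attempts,
                 " attempts (need ", params$n_select, ")")
      }
      sel <- pool[sample.int(nrow(pool), params$n_select), , drop = FALSE]
      data.frame(control_id = sprintf("%s_um%d", sites$site_id[i],
                                      seq_len(params$n_select)),
                 parent_site_id = sites$site_id[i],
                 chrom = sel$chrom, pos = sel$pos, kind = "umMRC",
                 dist_to_site = d_parent[i],
                 dist_to_active_gene = NA_integer_,
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Generate active-gene matched random controls (agMRC)
#'
#' Adds a second level of matching on top of [generate_ummrc()]: per site,
#' `n_candidates_ag` umMRC candidates are generated, the distance of each
#' candidate to the nearest active gene body (0 inside a body) is computed,
#' candidates are ranked by the absolute difference from the site's own
#' active-gene distance, and the `n_select` best are returned. Ties at the
#' selection boundary are broken uniformly at random under the seed.
#'
#' @inheritParams generate_ummrc
#' @param active_genes Interval data.frame of active gene bodies (e.g.
#'   active rows of the annotation's gene table).
#' @param keep_candidates If `TRUE`, the full per-site candidate pools are
#'   attached as attribute `"candidates"` (a named list of data.frames with
#'   the candidate positions and their active-gene distances).
#' @return Control data.frame with kind `"agMRC"` and the matched
#'   `dist_to_active_gene` filled in.
#' @export
generate_agmrc <- function(sites, active_genes, genome, site_index,
                           params = control_params(), seed = NULL,
                           keep_candidates = FALSE) {
  if (is.null(active_genes) || nrow(active_genes) == 0L) {
    stop_bad("no active genes: agMRC matching is undefined")
  }
  active_genes <- as_intervals(active_genes[c("chrom", "start", "end")],
                               "active genes")
  chrom_lens <- stats::setNames(Biostrings::width(genome), names(genome))
  d_parent <- site_parent_distances(sites, site_index)
  d_gene_site <- point_interval_distance(sites$chrom, sites$pos, active_genes)
  if (anyNA(d_gene_site)) {
    stop_bad("some sites lie on chromosomes without active genes")
  }
  seeds <- derive_seeds(seed, sites$site_id)
  ord <- order(sites$site_id)
  cand_pools <- list()
  out <- lapply(ord, function(i) {
    with_seed(seeds[[sites$site_id[i]]], {
      pool <- draw_candidates(d_parent[i], site_index, genome, chrom_lens,
                              params$n_candidates_ag, params)
      if (nrow(pool) < params$n_select) {
        stop_bad("site ", sites$site_id[i], ": only ", nrow(pool),
                 " matched candidates after ", params$max_attempts,
                 " attempts (need ", params$n_select, ")")
      }
      pool$dist_to_active_gene <-
        point_interval_distance(pool$chrom, pool$pos, active_genes)
      pool <- pool[!is.na(pool$dist_to_active_gene), , drop = FALSE]
      delta <- abs(pool$dist_to_active_gene - d_gene_site[i])
      sel_ord <- order(delta, stats::runif(nrow(pool)))
      sel <- pool[sel_ord[seq_len(params$n_select)], , drop = FALSE]
      if (keep_candidates) {
        pool$abs_delta <- delta
        cand_pools[[sites$site_id[i]]] <<- pool
      }
      data.frame(control_id = sprintf("%s_ag%d", sites$site_id[i],
                                      seq_len(params$n_select)),
                 parent_site_id = sites$site_id[i],
                 chrom = sel$chrom, pos = sel$pos, kind = "agMRC",
                 dist_to_site = d_parent[i],
                 dist_to_active_gene = sel$dist_to_active_gene,
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (keep_candidates) attr(out, "candidates") <- cand_pools
  out
}
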