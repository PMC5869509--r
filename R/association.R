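# Distances, targeting frequencies and orientations of sites and controls
# relative to annotation tracks.

query_ids <- function(positions) {
  positions$query_id %||% positions$site_id %||% positions$control_id %||%
    sprintf("q%04d", seq_len(nrow(positions)))
}

#' Distance to the nearest feature interval
#'
#' For each query position, the distance to the nearest interval of the
#' feature track on the same chromosome: 0 when the position lies inside an
#' interval, otherwise the gap to the nearest covered base
#' (`max(start - pos, pos - (end - 1), 0)` minimized over intervals).
#' Positions on chromosomes with no features get `NA` (they are counted in
#' a message and excluded from tests downstream). Features of other
#' chromosomes are never "nearest".
#'
#' @param positions data.frame with `chrom`, `pos` and an id column
#'   (`site_id`, `control_id` or `query_id`).
#' @param features Sorted disjoint interval data.frame.
#' @param feature_track Track label recorded in the output.
#' @return data.frame with `query_id`, `feature_track`, `distance`,
#'   `signed_distance` (`NA`; filled by TSS-relative analyses), `inside`.
#' @export
nearest_distance <- function(positions, features, feature_track = "feature") {
  d <- point_interval_distance(positions$chrom, positions$pos, features)
  if (anyNA(d)) {
    message(sum(is.na(d)), " position(s) on chromosomes without '",
            feature_track, "' features (distance NA)")
  }
  data.frame(query_id = query_ids(positions),
             feature_track = feature_track,
             distance = d,
             signed_distance = NA_integer_,
             inside = !is.na(d) & d == 0L,
             stringsAsFactors = FALSE)
}

#' Signed position relative to a TSS
#'
#' Signed distance in the gene's reading direction: positive downstream of
#' the TSS, negative upstream. `pos - tss` for `+` genes, `tss - pos` for
#' `-` genes.
#'
#' @param pos Integer position(s).
#' @param tss Integer TSS base(s).
#' @param strand Gene strand(s), `"+"` or `"-"`.
#' @return Signed integer distance(s) in bp.
#' @examples
#' tss_relative_position(1100, 1000, "+")  # +100, downstream
#' tss_relative_position(1100, 1000, "-")  # -100, upstream
#' @export
tss_relative_position <- function(pos, tss, strand) {
  stopifnot(all(strand %in% c("+", "-")))
  as.integer(ifelse(strand == "+", pos - tss, tss - pos))
}

#' Distance to the nearest TSS
#'
#' Absolute and signed distance from each query position to the nearest TSS
#' of the gene set (nearest by absolute distance; the sign follows that
#' gene's strand). `|signed_distance|` always equals `distance`.
#'
#' @inheritParams nearest_distance
#' @param genes Gene data.frame with `tss` and `strand` columns.
#' @return data.frame as in [nearest_distance()] with `signed_distance`
#'   filled and `feature_track = "TSS"` by default.
#' @export
nearest_tss_distance <- function(positions, genes, feature_track = "TSS") {
  out <- data.frame(query_id = query_ids(positions),
                    feature_track = feature_track,
                    distance = NA_integer_,
                    signed_distance = NA_integer_,
                    inside = FALSE, stringsAsFactors = FALSE)
  for (ch in unique(positions$chrom)) {
    gi <- which(genes$chrom == ch)
    qi <- which(positions$chrom == ch)
    if (length(gi) == 0L) next
    tss <- genes$tss[gi]
    strand <- genes$strand[gi]
    o <- order(tss)
    tss <- tss[o]; strand <- strand[o]
    p <- positions$pos[qi]
    k <- findInterval(p, tss)
    left <- pmax(k, 1L)
    right <- pmin(k + 1L, length(tss))
    use_right <- k == 0L | (k < length(tss) & (tss[right] - p) < (p - tss[left]))
    j <- ifelse(use_right, right, left)
    out$distance[qi] <- abs(p - tss[j])
    out$signed_distance[qi] <- tss_relative_position(p, tss[j], strand[j])
    out$inside[qi] <- out$distance[qi] == 0L
  }
  if (anyNA(out$distance)) {
    message(sum(is.na(out$distance)),
            " position(s) on chromosomes without genes (distance NA)")
  }
  out
}

#' Fraction of positions inside a feature track
#'
#' @inheritParams nearest_distance
#' @return List with `count_in` and `fraction`.
#' @examples
#' feats <- data.frame(chrom = "chr1", start = 10, end = 20)
#' pos <- data.frame(chrom = "chr1", pos = c(5, 15, 25))
#' in_feature_fraction(pos, feats)
#' @export
in_feature_fraction <- function(positions, features) {
  if (nrow(positions) == 0L) stop_bad("empty position set")
  inside <- point_in_intervals(positions$chrom, positions$pos, features)
  list(count_in = sum(inside), fraction = mean(inside))
}

#' Assign each site to its host gene
#'
#' The gene whose body contains the position; when several genes overlap
#' the position, the one with the nearest TSS wins (ties broken by gene_id
#' order, deterministically). Intergenic positions get `NA`.
#'
#' @param sites data.frame with `chrom`, `pos`.
#' @param genes Gene data.frame.
#' @return Character vector of `gene_id` or `NA` per site.
#' @export
assign_host_gene <- function(sites, genes) {
  vapply(seq_len(nrow(sites)), function(i) {
    hit <- which(genes$chrom == sites$chrom[i] &
                   genes$start <= sites$pos[i] & sites$pos[i] < genes$end)
    if (length(hit) == 0L) return(NA_character_)
    if (length(hit) > 1L) {
      dtss <- abs(sites$pos[i] - genes$tss[hit])
      hit <- hit[order(dtss, genes$gene_id[hit])]
    }
    genes$gene_id[hit[1L]]
  }, character(1L))
}

#' Provirus orientation relative to the host gene
#'
#' `"sense"` when the provirus strand equals the host gene strand,
#' `"antisense"` otherwise. Every site must lie inside a gene body; an
#' intergenic site is an error (orientation is undefined there — filter
#' with [assign_host_gene()] first).
#'
#' @param sites Site data.frame with `strand`.
#' @param genes Gene data.frame.
#' @return Character vector, `"sense"`/`"antisense"` per site.
#' @export
classify_orientation <- function(sites, genes) {
  host <- assign_host_gene(sites, genes)
  if (anyNA(host)) {
    stop_bad("site(s) not inside any gene: ",
             paste(sites$site_id[is.na(host)] %||%
                     which(is.na(host)), collapse = ", "))
  }
  gstrand <- genes$strand[match(host, genes$gene_id)]
  ifelse(sites$strand == gstrand, "sense", "antisense")
}

#' Sense/antisense counts for the intragenic subset of a cohort
#'
#' Convenience wrapper: assigns host genes, drops intergenic sites and
#' counts orientations.
#'
#' @inheritParams classify_orientation
#' @return List with `sense`, `antisense`, `n_intragenic`.
#' @export
orientation_counts <- function(sites, genes) {
  host <- assign_host_gene(sites, genes)
  inside <- sites[!is.na(host), , drop = FALSE]
  if (nrow(inside) == 0L) {
    return(list(sense = 0L, antisense = 0L, n_intragenic = 0L))
  }
  ori <- classify_orientation(inside, genes)
  list(sense = sum(ori == "sense"), antisense = sum(ori == "antisense"),
       n_intragenic = nrow(inside))
}
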