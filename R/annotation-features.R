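# Chromatin-state vocabulary and merged-group definitions. The Regulatory
# group is the 11 promoter/enhancer/open-chromatin states; the Active group
# adds the 7 transcription-associated states. The remaining 7 states
# (CTCF-bound, repressed, quiescent, artefact) complete the 25-state
# vocabulary.
REGULATORY_STATES <- c("Tss", "TssF", "PromF", "PromP", "Enh", "EnhF",
                       "EnhW", "EnhWF", "DnaseD", "DnaseU", "FaireW")
ACTIVE_STATES <- c(REGULATORY_STATES,
                   "Gen5", "Elon", "ElonW", "ElonWF", "Gen3", "H4K20", "Low")
OTHER_STATES <- c("Ctcf", "CtcfO", "Repr", "ReprD", "ReprW", "Quies", "Art")

#' The 25-label chromatin-state vocabulary
#'
#' State labels of the HMM-based 25-state segmentation the segment tracks
#' are expected to use. The vocabulary is configuration: pass a custom
#' vector to the `vocabulary` argument of [merge_chromatin_segments()] for
#' tracks with other label sets.
#'
#' @return Character vector of 25 state labels.
#' @export
chromatin_state_vocabulary <- function() c(ACTIVE_STATES, OTHER_STATES)

#' Segment group definition
#'
#' `"Active"` comprises the 18 transcription/promoter/enhancer-associated
#' states; `"Regulatory"` the 11 promoter/enhancer states. A custom group is
#' a list with `group_name` and `member_states`.
#'
#' @param group_name `"Active"` or `"Regulatory"`.
#' @return List with `group_name` and `member_states`.
#' @export
segment_group <- function(group_name = c("Active", "Regulatory")) {
  group_name <- match.arg(group_name)
  list(group_name = group_name,
       member_states = switch(group_name, Active = ACTIVE_STATES,
                              Regulatory = REGULATORY_STATES))
}

#' Call active genes from three evidence classes
#'
#' A gene is active if its TSS base (i) lies inside an H3K4me3 peak, or
#' (ii) lies inside a `Tss` chromatin segment, or (iii) is within
#' `cage_window` bp of the nearest CAGE peak TSS. The CAGE peak TSS is
#' operationalized as the peak interval midpoint (configurable to the 5'
#' end). The three criterion-specific flags are returned separately along
#' with their union, because the three active-gene sets are analysed
#' separately downstream.
#'
#' @param genes Gene data.frame (with `tss` column).
#' @param h3k4me3_peaks,cage_peaks Peak interval data.frames (may be `NULL`
#'   or empty: the corresponding flag is all-`FALSE`).
#' @param tss_segments Segment data.frame; if a `state` column is present it
#'   is filtered to `state == "Tss"`.
#' @param cage_window Maximum TSS-to-CAGE distance in bp (inclusive).
#' @param cage_point Reference point of a CAGE peak: `"midpoint"` (default)
#'   or `"five_prime"` (the interval start).
#' @return data.frame with columns `gene_id`, `active_by_h3k4me3`,
#'   `active_by_tss_segment`, `active_by_cage`, `active_any`.
#' @export
call_active_genes <- function(genes, h3k4me3_peaks = NULL,
                              tss_segments = NULL, cage_peaks = NULL,
                              cage_window = 500L,
                              cage_point = c("midpoint", "five_prime")) {
  cage_point <- match.arg(cage_point)
  empty <- function(x) is.null(x) || nrow(x) == 0L
  by_h3k4me3 <- if (empty(h3k4me3_peaks)) {
    rep(FALSE, nrow(genes))
  } else {
    point_in_intervals(genes$chrom, genes$tss, h3k4me3_peaks)
  }
  if (!empty(tss_segments) && "state" %in% names(tss_segments)) {
    tss_segments <- tss_segments[tss_segments$state == "Tss", , drop = FALSE]
  }
  by_tss_seg <- if (empty(tss_segments)) {
    rep(FALSE, nrow(genes))
  } else {
    point_in_intervals(genes$chrom, genes$tss, tss_segments)
  }
  by_cage <- if (empty(cage_peaks)) {
    rep(FALSE, nrow(genes))
  } else {
    pt <- if (cage_point == "midpoint") {
      (cage_peaks$start + cage_peaks$end - 1L) %/% 2L
    } else {
      cage_peaks$start
    }
    d <- point_interval_distance(genes$chrom, genes$tss,
                                 data.frame(chrom = cage_peaks$chrom,
                                            start = pt, end = pt + 1L))
    !is.na(d) & d <= cage_window
  }
  data.frame(gene_id = genes$gene_id,
             active_by_h3k4me3 = by_h3k4me3,
             active_by_tss_segment = by_tss_seg,
             active_by_cage = by_cage,
             active_any = by_h3k4me3 | by_tss_seg | by_cage,
             stringsAsFactors = FALSE)
}

#' Merge chromatin segments into a group track
#'
#' Keeps the segments whose state belongs to the group, then merges
#' overlapping and bookended (end == start) intervals into a sorted,
#' disjoint track. Unknown state labels are an error (vocabulary guard
#' against mislabelled tracks).
#'
#' @param segments Segment data.frame with a `state` column.
#' @param group Group from [segment_group()] (or a compatible list).
#' @param vocabulary Permitted state labels.
#' @return Sorted disjoint interval data.frame.
#' @examples
#' segs <- data.frame(chrom = "chr1", start = c(100, 200), end = c(200, 300),
#'                    state = c("Enh", "EnhF"))
#' merge_chromatin_segments(segs, segment_group("Regulatory"))
#' @export
merge_chromatin_segments <- function(segments, group = segment_group("Active"),
                                     vocabulary =
                                       chromatin_state_vocabulary()) {
  unknown <- setdiff(unique(segments$state), vocabulary)
  if (length(unknown) > 0L) {
    stop_bad("unknown chromatin state label(s): ",
             paste(unknown, collapse = ", "))
  }
  keep <- segments[segments$state %in% group$member_states, , drop = FALSE]
  merge_intervals(keep, bookended = TRUE)
}

#' Classify gene expression activity
#'
#' Genes with RPKM < 1 form the `NA` class (no or very low transcription);
#' the remaining genes are split into quartiles `Q1` (lowest) to `Q4`
#' (highest) of RPKM rank, with ties resolved by stable input order so that
#' quartile sizes differ by at most one.
#'
#' @param genes Gene data.frame with an `rpkm` column (no missing values).
#' @return data.frame with columns `gene_id`, `class`.
#' @export
classify_gene_activity <- function(genes) {
  if (anyNA(genes$rpkm)) stop_bad("rpkm must be present for all genes")
  cls <- rep("NA", nrow(genes))
  expressed <- which(genes$rpkm >= 1)
  if (length(expressed) == 0L) {
    warning("no gene with RPKM >= 1; all genes classified NA", call. = FALSE)
  } else {
    ord <- expressed[order(genes$rpkm[expressed])]  # stable for ties
    q <- ceiling(seq_along(ord) * 4 / length(ord))
    cls[ord] <- paste0("Q", q)
  }
  data.frame(gene_id = genes$gene_id, class = cls, stringsAsFactors = FALSE)
}
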