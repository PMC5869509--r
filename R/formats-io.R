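#' Read a BED-like interval track
#'
#' Reads BED3/BED6 intervals, chromatin-segment BED (name column carries the
#' state label) or peak BED. All coordinates are kept 0-based half-open,
#' exactly as in the file. Malformed lines are fatal: silently skipping
#' records would corrupt matched-control statistics downstream.
#'
#' @param path Path to a tab-separated BED-like file without header.
#' @param track_kind One of `"bed3"`, `"bed6"`, `"segment_bed"`,
#'   `"peak_bed"`. For `"segment_bed"` the 4th column becomes the `state`
#'   column; for `"peak_bed"` overlapping intervals are merged after loading
#'   (a peak track is a coverage mask, not a multiset) and the `mark` column
#'   is filled from `mark`.
#' @param mark Mark label attached to peak tracks (default: file base name).
#' @param one_based Set `TRUE` for 1-based closed input coordinates; they are
#'   converted to the 0-based half-open internal convention on load.
#' @return A data.frame with columns `chrom`, `start`, `end` plus
#'   `strand` (bed6), `state` (segment_bed) or `mark` (peak_bed), sorted by
#'   `(chrom, start)`.
#' @examples
#' p <- tempfile(fileext = ".bed")
#' writeLines("chr1\t10\t20\tEnh", p)
#' read_intervals(p, "segment_bed")
#' @export
read_intervals <- function(path, track_kind = c("bed3", "bed6", "segment_bed",
                                                "peak_bed"),
                           mark = NULL, one_based = FALSE) {
  track_kind <- match.arg(track_kind)
  if (!file.exists(path)) stop_bad("file not found: ", path)
  min_cols <- switch(track_kind, bed3 = 3L, peak_bed = 3L,
                     segment_bed = 4L, bed6 = 6L)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "", fill = TRUE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < min_cols) {
    stop_bad(path, ": ", track_kind, " needs >= ", min_cols, " columns")
  }
  start <- suppressWarnings(as.integer(raw[[2L]]))
  end <- suppressWarnings(as.integer(raw[[3L]]))
  if (anyNA(start) || anyNA(end)) {
    stop_bad(path, ": non-integer coordinate column")
  }
  if (one_based) start <- start - 1L
  df <- data.frame(chrom = raw[[1L]], start = start, end = end,
                   stringsAsFactors = FALSE)
  if (track_kind == "bed6") df$strand <- raw[[6L]]
  if (track_kind == "segment_bed") df$state <- raw[[4L]]
  df <- as_intervals(df, what = path)
  if (track_kind == "segment_bed") check_string(df$state, "state")
  if (track_kind == "peak_bed") {
    df <- merge_intervals(df, bookended = FALSE)
    df$mark <- mark %||% sub("\\.[^.]*$", "", basename(path))
  }
  df
}

#' Write an interval track as BED
#'
#' Emits `chrom`, `start`, `end` and, when present, a name column taken from
#' `state` or `mark`, and a `strand` column (BED6 layout with score 0).
#' Coordinates are written unchanged (0-based half-open), so
#' [read_intervals()] round-trips exactly.
#'
#' @param intervals Interval data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  name <- intervals$state %||% intervals$mark %||% rep(".", nrow(intervals))
  cols <- list(intervals$chrom, intervals$start, intervals$end, name)
  if (!is.null(intervals$strand)) {
    cols <- c(cols, list(rep(0L, nrow(intervals)), intervals$strand))
  }
  tab <- do.call(cbind.data.frame, c(cols, stringsAsFactors = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read integration sites
#'
#' Reads a header TSV of provirus integration sites. Each site is the single
#' LTR-proximal base of a mapped provirus-host junction; its strand is the
#' provirus orientation, required for sense/antisense analysis. Duplicate
#' positions from different clones are distinct sites (clones are the
#' experimental unit), but `site_id` values are keys and must be unique.
#'
#' @param path TSV with header columns `site_id`, `chrom`, `pos`, `strand`,
#'   `vector`, `clone_id`.
#' @param one_based Set `TRUE` if `pos` is 1-based; converted on load.
#' @return data.frame with those six columns; `pos` is the 0-based
#'   integration base.
#' @export
read_sites <- function(path, one_based = FALSE) {
  if (!file.exists(path)) stop_bad("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  need <- c("site_id", "chrom", "pos", "strand", "vector", "clone_id")
  if (!all(need %in% names(df))) {
    stop_bad(path, ": site table needs columns ", paste(need, collapse = ", "))
  }
  df <- df[need]
  df$pos <- suppressWarnings(as.integer(df$pos))
  validate_sites(df)
}

validate_sites <- function(df) {
  check_string(df$site_id, "site_id")
  if (anyDuplicated(df$site_id)) {
    stop_bad("duplicate site_id: ",
             df$site_id[anyDuplicated(df$site_id)])
  }
  check_string(df$chrom, "chrom")
  if (anyNA(df$pos) || any(df$pos < 0L)) {
    stop_bad("site pos must be a non-negative integer")
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop_bad("site strand must be + or - (provirus orientation is required)")
  }
  if (!all(df$vector %in% VECTOR_GROUPS)) {
    stop_bad("unknown vector label; expected one of ",
             paste(VECTOR_GROUPS, collapse = ", "))
  }
  rownames(df) <- NULL
  df
}

#' Write integration sites
#' @param sites Site data.frame as returned by [read_sites()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  cols <- c("site_id", "chrom", "pos", "strand", "vector", "clone_id")
  utils::write.table(sites[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a gene table
#'
#' Reads a simplified refGene-style TSV (`gene_id`, `chrom`, `start`, `end`,
#' `strand`, optional `rpkm`). Coordinates are declared 0-based half-open.
#' The TSS is derived from the strand: `start` for `+` genes and `end - 1`
#' (the last covered base) for `-` genes.
#'
#' @param path TSV path with header.
#' @param one_based Set `TRUE` for 1-based closed input coordinates.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`, `rpkm` (NA when absent), sorted by `(chrom, start)`.
#' @export
read_gene_table <- function(path, one_based = FALSE) {
  if (!file.exists(path)) stop_bad("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(df))) {
    stop_bad(path, ": gene table needs columns ", paste(need, collapse = ", "))
  }
  out <- data.frame(gene_id = df$gene_id, chrom = df$chrom,
                    start = suppressWarnings(as.integer(df$start)),
                    end = suppressWarnings(as.integer(df$end)),
                    strand = df$strand, stringsAsFactors = FALSE)
  if (one_based) out$start <- out$start - 1L
  out$rpkm <- if ("rpkm" %in% names(df)) {
    suppressWarnings(as.numeric(df$rpkm))
  } else {
    NA_real_
  }
  validate_genes(out)
}

validate_genes <- function(df) {
  check_string(df$gene_id, "gene_id")
  if (anyDuplicated(df$gene_id)) stop_bad("duplicate gene_id")
  if (!all(df$strand %in% c("+", "-"))) {
    stop_bad("gene strand must be + or - (a TSS needs a direction)")
  }
  if (!is.null(df$rpkm) && any(!is.na(df$rpkm) & df$rpkm < 0)) {
    stop_bad("rpkm must be non-negative")
  }
  df <- as_intervals(df, what = "gene table")
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  df
}

#' Write a gene table
#' @param genes Gene data.frame as returned by [read_gene_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  cols <- c("gene_id", "chrom", "start", "end", "strand", "rpkm")
  utils::write.table(genes[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a clone fluorescence table
#'
#' Reads a CSV of per-clone %GFP+ measurements: columns `clone_id`, `vector`
#' and one column per timepoint named `dpi<N>` (days post infection). Values
#' must lie in \[0, 100\]; missing per-clone values are allowed (the clonal
#' summaries exclude them per timepoint). A table with no `dpi` column is
#' accepted with a warning.
#'
#' @param path CSV path with header.
#' @return data.frame with `clone_id`, `vector` and numeric `dpi<N>` columns.
#' @export
read_clone_table <- function(path) {
  if (!file.exists(path)) stop_bad("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("clone_id", "vector")
  if (!all(need %in% names(df))) {
    stop_bad(path, ": clone table needs columns clone_id, vector")
  }
  dpi_cols <- grep("^dpi[0-9]+$", names(df), value = TRUE)
  if (length(dpi_cols) == 0L) {
    warning("clone table ", path, " has no dpi<N> columns", call. = FALSE)
  }
  tp <- as.integer(sub("^dpi", "", dpi_cols))
  if (any(tp <= 0L)) stop_bad("timepoints must be strictly positive dpi")
  out <- df[c(need, dpi_cols)]
  for (cc in dpi_cols) {
    v <- suppressWarnings(as.numeric(out[[cc]]))
    if (any(!is.na(v) & (v < 0 | v > 100))) {
      stop_bad(path, ": %GFP+ value outside [0, 100] in column ", cc)
    }
    out[[cc]] <- v
  }
  validate_clones(out)
}

validate_clones <- function(df) {
  check_string(df$clone_id, "clone_id")
  if (anyDuplicated(df$clone_id)) stop_bad("duplicate clone_id")
  if (!all(df$vector %in% VECTOR_GROUPS)) {
    stop_bad("unknown vector label in clone table")
  }
  rownames(df) <- NULL
  df
}

#' Write a clone fluorescence table
#' @param clones Clone data.frame as returned by [read_clone_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_clone_table <- function(clones, path) {
  utils::write.csv(clones, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a matched-control table
#'
#' Matched random controls are stored as TSV with columns `control_id`,
#' `parent_site_id`, `chrom`, `pos`, `kind` (`umMRC` or `agMRC`),
#' `dist_to_site` (matched distance to the nearest restriction-enzyme
#' recognition site) and `dist_to_active_gene` (agMRC only, NA otherwise).
#'
#' @param path TSV path.
#' @return For `read_controls`, the control data.frame.
#' @export
read_controls <- function(path) {
  if (!file.exists(path)) stop_bad("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("control_id", "parent_site_id", "chrom", "pos", "kind",
            "dist_to_site", "dist_to_active_gene")
  if (!all(need %in% names(df))) {
    stop_bad(path, ": control table needs columns ",
             paste(need, collapse = ", "))
  }
  if (!all(df$kind %in% c("umMRC", "agMRC"))) {
    stop_bad("control kind must be umMRC or agMRC")
  }
  if (any(df$dist_to_site < 0L)) stop_bad("dist_to_site must be >= 0")
  if (any(df$kind == "agMRC" & is.na(df$dist_to_active_gene))) {
    stop_bad("agMRC rows need dist_to_active_gene")
  }
  df[need]
}

#' @rdname read_controls
#' @param controls Control data.frame.
#' @export
write_controls <- function(controls, path) {
  cols <- c("control_id", "parent_site_id", "chrom", "pos", "kind",
            "dist_to_site", "dist_to_active_gene")
  utils::write.table(controls[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
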