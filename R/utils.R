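# Internal helpers shared across modules. All genomic coordinates in this
# package are 0-based, half-open [start, end): BED-native, so BED tracks are
# read and written without any shift.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a temporary RNG state
#'
#' Runs `code` with the RNG seeded to `seed`, then restores the caller's
#' global RNG state, so seeded simulations never perturb the session stream.
#' With `seed = NULL` the code runs on the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive one sub-seed per key from a master seed, independent of key order.
# Keys are sorted so results are invariant to input permutation; values stay
# below 2^31.
derive_seeds <- function(seed, keys) {
  if (is.null(seed)) return(stats::setNames(rep(list(NULL), length(keys)), keys))
  ord <- order(keys)
  subs <- with_seed(seed, sample.int(.Machine$integer.max - 1L, length(keys)))
  out <- integer(length(keys))
  out[ord] <- subs
  stats::setNames(as.list(out), keys)
}

stop_bad <- function(...) stop(..., call. = FALSE)

check_string <- function(x, what) {
  if (!is.character(x) || anyNA(x) || any(!nzchar(x))) {
    stop_bad(what, " must be non-empty character values")
  }
  invisible(x)
}

VECTOR_GROUPS <- c("ASLV", "HIV", "MLV", "other")

# --- interval containers ----------------------------------------------------

# Canonical interval data.frame: chrom, start, end (+ optional strand/state/
# mark columns). Validates the 0 <= start < end invariant and sorts by
# (chrom, start, end).
as_intervals <- function(df, what = "intervals") {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df))) {
    stop_bad(what, " must have columns chrom, start, end")
  }
  df$chrom <- as.character(df$chrom)
  check_string(df$chrom, paste0(what, ": chrom"))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (anyNA(df$start) || anyNA(df$end)) {
    stop_bad(what, ": non-integer start/end coordinate")
  }
  if (any(df$start < 0L)) stop_bad(what, ": negative start coordinate")
  if (any(df$start >= df$end)) {
    bad <- which(df$start >= df$end)[1L]
    stop_bad(what, ": start >= end at ", df$chrom[bad], ":", df$start[bad],
             "-", df$end[bad])
  }
  if ("strand" %in% names(df)) {
    if (!all(df$strand %in% c("+", "-", "."))) {
      stop_bad(what, ": strand must be one of +, -, .")
    }
  }
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

sort_intervals <- function(df) {
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Merge overlapping and (optionally) bookended intervals into a disjoint,
# sorted set. Extra columns are dropped.
merge_intervals <- function(df, bookended = TRUE) {
  if (nrow(df) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  df <- sort_intervals(df[c("chrom", "start", "end")])
  out_chrom <- character(0); out_start <- integer(0); out_end <- integer(0)
  cur_chrom <- df$chrom[1L]; cur_start <- df$start[1L]; cur_end <- df$end[1L]
  if (nrow(df) > 1L) {
    for (i in 2L:nrow(df)) {
      joins <- df$chrom[i] == cur_chrom &&
        (df$start[i] < cur_end || (bookended && df$start[i] == cur_end))
      if (joins) {
        cur_end <- max(cur_end, df$end[i])
      } else {
        out_chrom <- c(out_chrom, cur_chrom)
        out_start <- c(out_start, cur_start)
        out_end <- c(out_end, cur_end)
        cur_chrom <- df$chrom[i]; cur_start <- df$start[i]; cur_end <- df$end[i]
      }
    }
  }
  data.frame(chrom = c(out_chrom, cur_chrom),
             start = c(out_start, cur_start),
             end = c(out_end, cur_end),
             stringsAsFactors = FALSE)
}

# Distance from single-base positions to the nearest interval of a disjoint,
# sorted feature set on the same chromosome:
#   d = max(start - pos, pos - (end - 1), 0)
# minimized over intervals; 0 iff the position is covered. Positions on
# chromosomes with no features get NA.
point_interval_distance <- function(chrom, pos, features) {
  stopifnot(length(chrom) == length(pos))
  out <- rep(NA_integer_, length(pos))
  if (nrow(features) == 0L || length(pos) == 0L) return(out)
  features <- sort_intervals(features[c("chrom", "start", "end")])
  by_chrom <- split(seq_len(nrow(features)), features$chrom)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    f <- by_chrom[[ch]]
    if (is.null(f)) next
    starts <- features$start[f]
    ends <- features$end[f]
    p <- pos[idx]
    k <- findInterval(p, starts)   # last interval with start <= pos (0 if none)
    d_left <- ifelse(k >= 1L,
                     pmax(p - (ends[pmax(k, 1L)] - 1L), 0L),
                     NA_integer_)
    kn <- k + 1L
    d_right <- ifelse(kn <= length(starts), starts[pmin(kn, length(starts))] - p,
                      NA_integer_)
    out[idx] <- pmin(d_left, d_right, na.rm = TRUE)
  }
  as.integer(out)
}

# TRUE where a position falls inside some interval of the track.
point_in_intervals <- function(chrom, pos, features) {
  d <- point_interval_distance(chrom, pos, features)
  !is.na(d) & d == 0L
}

# Distance from positions to the nearest position in a sorted integer vector
# (same chromosome). Used for restriction-site distances.
point_point_distance <- function(pos, site_positions) {
  if (length(site_positions) == 0L) {
    stop_bad("no recognition sites available on this chromosome")
  }
  s <- sort(site_positions)
  k <- findInterval(pos, s)
  d_left <- ifelse(k >= 1L, pos - s[pmax(k, 1L)], NA_real_)
  d_right <- ifelse(k < length(s), s[pmin(k + 1L, length(s))] - pos, NA_real_)
  as.integer(pmin(d_left, d_right, na.rm = TRUE))
}
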