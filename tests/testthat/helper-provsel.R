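# Fixture builders and independent brute-force oracles used across the
# suite. Oracles deliberately avoid the code paths they check.

tiny_genome <- function(...) {
  seqs <- c(...)
  g <- Biostrings::DNAStringSet(unname(seqs))
  names(g) <- names(seqs)
  g
}

make_genes <- function(gene_id, chrom, start, end, strand, rpkm = NA_real_) {
  df <- data.frame(gene_id = gene_id, chrom = chrom, start = start,
                   end = end, strand = strand, rpkm = rpkm,
                   stringsAsFactors = FALSE)
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  df
}

make_sites <- function(chrom, pos, strand = "+", vector = "other",
                       prefix = "s") {
  n <- max(length(chrom), length(pos))
  data.frame(site_id = sprintf("%s%03d", prefix, seq_len(n)),
             chrom = chrom, pos = as.integer(pos), strand = strand,
             vector = vector,
             clone_id = sprintf("c%03d", seq_len(n)),
             stringsAsFactors = FALSE)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

# Brute force: distance from a point to the nearest covered base of a set
# of intervals on the same chromosome (enumerates covered bases).
bf_point_distance <- function(chrom, pos, features) {
  f <- features[features$chrom == chrom, , drop = FALSE]
  if (nrow(f) == 0L) return(NA_integer_)
  covered <- unlist(lapply(seq_len(nrow(f)), function(i) {
    f$start[i]:(f$end[i] - 1L)
  }))
  min(abs(covered - pos))
}

# Brute force: two-sided Fisher p by explicit enumeration of all tables
# with the observed margins, probabilities via lchoose (not dhyper).
bf_fisher_p <- function(a, b, c_, d) {
  n <- a + b + c_ + d
  m <- a + b
  k <- a + c_
  support <- max(0, k - (n - m)):min(k, m)
  logp <- lchoose(m, support) + lchoose(n - m, k - support) - lchoose(n, k)
  probs <- exp(logp)
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Brute force: exact two-sided signed-rank p by full 2^n sign-flip
# enumeration on the average ranks of |d|.
bf_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_le <- mean(v_all <= v_obs + 1e-9)
  p_ge <- mean(v_all >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Brute force: sliding-window ungapped identity scan counting genome-wide
# occurrences of a fragment at >= min_identity over full length, both
# strands.
bf_count_occurrences <- function(frag, genome, min_identity) {
  frag <- toupper(frag)
  L <- nchar(frag)
  k_max <- L - ceiling(min_identity * L)
  fv <- strsplit(frag, "")[[1]]
  rc <- chartr("ACGT", "TGCA", paste(rev(fv), collapse = ""))
  rv <- strsplit(rc, "")[[1]]
  total <- 0L
  for (ci in seq_along(genome)) {
    s <- strsplit(as.character(genome[[ci]]), "")[[1]]
    if (length(s) < L) next
    for (start in 1:(length(s) - L + 1L)) {
      win <- s[start:(start + L - 1L)]
      if (sum(win != fv) <= k_max) total <- total + 1L
      if (frag != rc && sum(win != rv) <= k_max) total <- total + 1L
    }
  }
  total
}

# Uniform random positions over a genome's chromosomes.
uniform_positions <- function(n, chrom_lengths, prefix = "q") {
  ch <- sample(names(chrom_lengths), n, replace = TRUE,
               prob = chrom_lengths)
  data.frame(query_id = sprintf("%s%04d", prefix, seq_len(n)),
             chrom = ch,
             pos = vapply(ch, function(c2) {
               sample.int(chrom_lengths[[c2]], 1L) - 1L
             }, integer(1L)),
             stringsAsFactors = FALSE)
}

# Small shared simulated study (genome + annotation + enzyme index),
# memoised per test run.
study_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- simulate_genome(3L, 100000L, seed = 401L)
      ann <- simulate_annotation(g, seed = 402L)
      idx <- scan_recognition_sites(g, restriction_motifs(c("NlaIII",
                                                            "MseI")))
      cache <<- list(genome = g, annotation = ann, index = idx)
    }
    cache
  }
})
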