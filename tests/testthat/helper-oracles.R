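# Brute-force, per-base oracles kept deliberately independent of the
# package's run-length arithmetic: every quantity is computed by
# expanding coverage to one value per base pair.

# depth at every base of [from, to) as a plain vector
oracle_depth_vector <- function(track, chrom, from, to) {
  v <- numeric(to - from)
  runs <- track[track$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(runs))) {
    lo <- max(runs$start[i], from); hi <- min(runs$end[i], to)
    if (hi > lo) v[(lo - from + 1):(hi - from)] <- v[(lo - from + 1):(hi - from)] + runs$depth[i]
  }
  v
}

oracle_window_sum <- function(track, chrom, from, to) {
  sum(oracle_depth_vector(track, chrom, from, to))
}

# per-base threshold + gap-bridging + length-filter caller
oracle_call_units <- function(track, min_depth, max_gap, min_length) {
  out <- list()
  for (chrom in unique(track$chrom)) {
    runs <- track[track$chrom == chrom, , drop = FALSE]
    to <- max(runs$end)
    d <- oracle_depth_vector(track, chrom, 0, to)
    above <- d >= min_depth
    if (!any(above)) next
    # maximal above-threshold stretches
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths
    seg <- data.frame(start = starts[r$values], end = ends[r$values])
    # bridge gaps <= max_gap
    merged <- seg[1, ]
    for (i in seq_len(nrow(seg))[-1]) {
      if (seg$start[i] - merged$end[nrow(merged)] <= max_gap)
        merged$end[nrow(merged)] <- seg$end[i]
      else merged <- rbind(merged, seg[i, ])
    }
    merged <- merged[merged$end - merged$start >= min_length, , drop = FALSE]
    if (nrow(merged)) out[[chrom]] <- cbind(chrom = chrom, merged)
  }
  if (!length(out)) return(data.frame(chrom = character(),
                                      start = numeric(), end = numeric()))
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

# base-membership overlap count between two half-open intervals
oracle_overlap_bp <- function(s1, e1, s2, e2) {
  length(intersect(seq.int(s1, e1 - 1), seq.int(s2, e2 - 1)))
}

# random non-overlapping coverage runs on one chromosome
random_track <- function(n_runs = 20, span = 2000, strand = "+",
                         max_depth = 10, chrom = "chr1") {
  cuts <- sort(sample.int(span, min(2 * n_runs, span - 1)))
  starts <- cuts[seq(1, length(cuts) - 1, by = 2)]
  ends <- cuts[seq(2, length(cuts), by = 2)]
  keep <- ends > starts
  coverage_track(chrom, starts[keep], ends[keep],
                 sample.int(max_depth, sum(keep), replace = TRUE),
                 strand = strand)
}

# NB counts for a two-group design with per-feature log2 fold changes
nb_counts <- function(n_features, n_per_group = 4, mean_count = 200,
                      phi = 0.1, lfc = 0) {
  lfc <- rep_len(lfc, n_features)
  groups <- rep(c("A", "B"), each = n_per_group)
  mu <- outer(rep(mean_count, n_features), rep(1, 2 * n_per_group)) *
        2^(outer(lfc, as.numeric(groups == "B")))
  counts <- if (phi == 0) rpois(length(mu), mu)
            else rnbinom(length(mu), mu = mu, size = 1 / phi)
  counts <- matrix(counts, n_features, 2 * n_per_group)
  dimnames(counts) <- list(sprintf("f%04d", seq_len(n_features)),
                           paste0(groups, seq_len(2 * n_per_group)))
  count_matrix(counts, setNames(groups, colnames(counts)))
}

welch_perm_p <- function(a, b, B = 10000) {
  obs <- abs(t.test(a, b)$statistic)
  pool <- c(a, b); na <- length(a)
  hits <- 0
  for (i in seq_len(B)) {
    idx <- sample.int(length(pool), na)
    ti <- tryCatch(abs(t.test(pool[idx], pool[-idx])$statistic),
                   error = function(e) Inf)
    if (ti >= obs - 1e-12) hits <- hits + 1
  }
  (hits + 1) / (B + 1)
}
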