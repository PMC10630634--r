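# Strand-specific signal quantification over features: whole-gene,
# exonic/intronic partition, promoter-proximal pausing, RPKM.

#' Total coverage signal over a window
#'
#' Sums depth x overlapped-bp of every run intersecting the window, the
#' elementary quantity every quantification mode is built from.
#'
#' @param track A [coverage_track()].
#' @param chrom Chromosome name (matched as an exact string).
#' @param start,end Window, 0-based half-open.
#' @return Total signal in read-bp (numeric scalar).
#' @export
track_signal <- function(track, chrom, start, end) {
  runs <- track[track$chrom == chrom, , drop = FALSE]
  if (nrow(runs) == 0L) return(0)
  ov <- pmin(runs$end, end) - pmax(runs$start, start)
  sum(runs$depth[ov > 0] * ov[ov > 0])
}

region_complement <- function(start, end, sub) {
  # intervals of [start,end) not covered by the sorted sub-intervals
  if (nrow(sub) == 0L) return(data.frame(start = start, end = end))
  gaps_start <- c(start, sub$end)
  gaps_end <- c(sub$start, end)
  keep <- gaps_end > gaps_start
  data.frame(start = gaps_start[keep], end = gaps_end[keep])
}

#' Quantify features against strand-specific coverage
#'
#' Each feature's signal is the total depth-bp summed over the selected
#' regions, taken from the track matching the feature's strand only.
#' `mode = "gene"` uses the full interval, `"exon"` the exon union, and
#' `"intron"` the interval minus the exons, so that for every feature
#' exon + intron signal equals gene signal exactly.
#'
#' @param track_plus,track_minus [coverage_track()]s for the two strands.
#' @param features A [transcript_set()].
#' @param mode One of `"gene"`, `"exon"`, `"intron"`.
#' @return A data.frame with columns `id`, `signal` (read-bp), `bp`
#'   (region width).
#' @export
quantify_features <- function(track_plus, track_minus, features,
                              mode = c("gene", "exon", "intron")) {
  mode <- match.arg(mode)
  validate_transcripts(features)
  if (track_strand(track_plus) != "+" || track_strand(track_minus) != "-")
    stop("track_plus/track_minus must carry strands '+' and '-'")
  chroms <- unique(c(track_plus$chrom, track_minus$chrom))
  missing_chr <- setdiff(unique(features$chrom), chroms)
  if (length(missing_chr))
    warning("features on chromosomes absent from tracks (signal 0): ",
            paste(missing_chr, collapse = ", "))
  sig <- bp <- numeric(nrow(features))
  for (i in seq_len(nrow(features))) {
    track <- if (features$strand[i] == "+") track_plus else track_minus
    regions <- switch(mode,
      gene = data.frame(start = features$start[i], end = features$end[i]),
      exon = features$exons[[i]],
      intron = region_complement(features$start[i], features$end[i],
                                 features$exons[[i]]))
    if (nrow(regions)) {
      sig[i] <- sum(vapply(seq_len(nrow(regions)), function(k)
        track_signal(track, features$chrom[i], regions$start[k],
                     regions$end[k]), 0))
      bp[i] <- sum(regions$end - regions$start)
    }
  }
  data.frame(id = features$id, signal = sig, bp = bp,
             stringsAsFactors = FALSE)
}

#' Reads per kilobase per million mapped reads
#'
#' `RPKM = count / (length/1000) / (library_size/1e6)`. Log transforms
#' are applied downstream with a pseudocount of 1.
#'
#' @param counts Numeric matrix (features x samples) or vector.
#' @param lengths Feature lengths in bp (> 0), recycled across samples.
#' @param library_sizes Per-sample totals (> 0).
#' @return Matrix (or vector) of RPKM values.
#' @export
rpkm <- function(counts, lengths, library_sizes) {
  if (any(lengths <= 0)) stop("feature lengths must be > 0")
  if (any(library_sizes <= 0)) stop("library sizes must be > 0")
  if (is.matrix(counts)) {
    if (length(library_sizes) != ncol(counts))
      stop("need one library size per sample")
    sweep(counts / (lengths / 1000), 2, library_sizes / 1e6, "/")
  } else {
    counts / (lengths / 1000) / (library_sizes / 1e6)
  }
}

#' Promoter-proximal pausing signal
#'
#' Splits a gene into a promoter-proximal window (the first `window` bp
#' downstream of the TSS, in transcription direction, so
#' `[end - window, end)` for minus-strand genes) and the remaining gene
#' body, and reports signal densities plus their ratio. An elevated
#' ratio indicates RNA polymerase II accumulation near the promoter
#' relative to productive elongation.
#'
#' @param gene A single-row [transcript_set()] (or a row index into one).
#' @param track The [coverage_track()] for the gene's strand.
#' @param window Promoter-proximal width in bp (default 300).
#' @return A data.frame with `id`, `proximal_density`, `body_density`,
#'   `ratio` (NA when the body has zero signal).
#' @export
pausing_signal <- function(gene, track, window = 300) {
  validate_transcripts(gene)
  if (nrow(gene) != 1L) stop("pausing_signal expects a single gene")
  len <- gene$end - gene$start
  if (len <= window)
    stop("gene '", gene$id, "' (", len, " bp) is not longer than the ",
         window, " bp promoter-proximal window")
  if (track_strand(track) != gene$strand)
    stop("track strand does not match gene strand")
  if (gene$strand == "+") {
    prox <- c(gene$start, gene$start + window)
    body <- c(gene$start + window, gene$end)
  } else {
    prox <- c(gene$end - window, gene$end)
    body <- c(gene$start, gene$end - window)
  }
  ps <- track_signal(track, gene$chrom, prox[1], prox[2])
  bs <- track_signal(track, gene$chrom, body[1], body[2])
  pd <- ps / window
  bd <- bs / (len - window)
  data.frame(id = gene$id, proximal_density = pd, body_density = bd,
             ratio = if (bd > 0) pd / bd else NA_real_,
             stringsAsFactors = FALSE)
}

#' Compare pausing between two replicate groups
#'
#' Welch two-sample t tests applied separately to the promoter-proximal
#' densities and the gene-body densities, after scaling each replicate
#' to its library size (signal per million mapped reads).
#'
#' @param groupA,groupB Data.frames of [pausing_signal()] rows, one per
#'   replicate (at least 2 each).
#' @param libsizesA,libsizesB Optional per-replicate library sizes used
#'   to scale densities before testing; `NULL` leaves densities as-is.
#' @return A data.frame with one row per compartment (`proximal`,
#'   `body`): `t`, `df`, `p_value`, and the group means compared.
#' @export
compare_pausing <- function(groupA, groupB,
                            libsizesA = NULL, libsizesB = NULL) {
  if (nrow(groupA) < 2L || nrow(groupB) < 2L)
    stop("need at least 2 replicates per group")
  scale_to <- function(g, ls) {
    if (is.null(ls)) return(g)
    g$proximal_density <- g$proximal_density / ls * 1e6
    g$body_density <- g$body_density / ls * 1e6
    g
  }
  groupA <- scale_to(groupA, libsizesA)
  groupB <- scale_to(groupB, libsizesB)
  one <- function(col) {
    a <- groupA[[col]]; b <- groupB[[col]]
    if (var(a) == 0 && var(b) == 0 && mean(a) == mean(b))
      return(c(t = 0, df = length(a) + length(b) - 2, p = 1))
    tt <- t.test(a, b)
    c(t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value)
  }
  res <- rbind(one("proximal_density"), one("body_density"))
  data.frame(compartment = c("proximal", "body"),
             t = res[, "t"], df = res[, "df"], p_value = res[, "p"],
             mean_A = c(mean(groupA$proximal_density),
                        mean(groupA$body_density)),
             mean_B = c(mean(groupB$proximal_density),
                        mean(groupB$body_density)),
             stringsAsFactors = FALSE)
}
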