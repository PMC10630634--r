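# De novo transcription-unit calling from strand-specific nascent
# coverage, and merging of novel units into a reference annotation.

#' Parameters for the transcription-unit caller
#'
#' @param min_depth Depth threshold in reads/bp (> 0); positions at or
#'   above it are considered transcribed.
#' @param max_gap Maximum sub-threshold gap (bp) bridged inside one
#'   unit.
#' @param min_length Minimum unit length in bp; defaults to 200, the
#'   conventional lower bound for long noncoding RNAs.
#' @return A list of class `caller_params`.
#' @export
caller_params <- function(min_depth, max_gap = 500, min_length = 200) {
  if (min_depth <= 0) stop("min_depth must be > 0")
  if (max_gap < 0) stop("max_gap must be >= 0")
  if (min_length < 1) stop("min_length must be >= 1")
  structure(list(min_depth = min_depth, max_gap = max_gap,
                 min_length = min_length), class = "caller_params")
}

#' Default caller threshold from genome-wide mean depth
#'
#' `min_depth` defaults to 4x the genome-wide mean depth of the track
#' (total signal over total genome bp), a conservative threshold that
#' adapts to sequencing depth.
#'
#' @param track A [coverage_track()].
#' @param genome_bp Total genome size in bp over which the mean is taken.
#' @param ... Passed on to [caller_params()].
#' @return A `caller_params`.
#' @export
default_caller_params <- function(track, genome_bp, ...) {
  mean_depth <- sum(track$depth * (track$end - track$start)) / genome_bp
  if (mean_depth <= 0) stop("track has no signal; cannot derive min_depth")
  caller_params(min_depth = 4 * mean_depth, ...)
}

#' Call transcription units from strand-specific coverage
#'
#' Emits maximal runs with depth >= `min_depth`, bridging sub-threshold
#' gaps of at most `max_gap` bp, and discarding units shorter than
#' `min_length`. Units are single-exon (nascent coverage does not
#' resolve splicing), strand-tagged with the track strand, and get
#' deterministic ids `TU_<chrom>_<start>_<strand>`.
#'
#' @param track A [coverage_track()].
#' @param params A [caller_params()].
#' @return A [transcript_set()] with `source = "denovo"`,
#'   `biotype = "novel"`.
#' @export
call_transcription_units <- function(track, params) {
  stopifnot(inherits(params, "caller_params"))
  out <- list()
  for (chrom in unique(track$chrom)) {
    runs <- track[track$chrom == chrom & track$depth >= params$min_depth,
                  , drop = FALSE]
    if (nrow(runs) == 0L) next
    # coalesce adjacent/overlap-free above-threshold runs, then bridge
    s <- runs$start; e <- runs$end
    merged_s <- s[1]; merged_e <- e[1]
    if (nrow(runs) > 1L) {
      for (i in 2:nrow(runs)) {
        last <- length(merged_e)
        if (s[i] - merged_e[last] <= params$max_gap) {
          merged_e[last] <- max(merged_e[last], e[i])
        } else {
          merged_s <- c(merged_s, s[i]); merged_e <- c(merged_e, e[i])
        }
      }
    }
    keep <- (merged_e - merged_s) >= params$min_length
    if (!any(keep)) next
    out[[chrom]] <- data.frame(chrom = chrom, start = merged_s[keep],
                               end = merged_e[keep])
  }
  if (length(out) == 0L)
    return(transcript_set(character(), character(), numeric(),
                          numeric(), character()))
  df <- do.call(rbind, out)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  strand <- track_strand(track)
  transcript_set(
    id = sprintf("TU_%s_%s_%s", df$chrom,
                 format(df$start, scientific = FALSE, trim = TRUE),
                 strand),
    chrom = df$chrom, start = df$start, end = df$end, strand = strand,
    biotype = "novel", source = "denovo")
}

#' Merge de novo units with a reference annotation
#'
#' A novel unit is dropped iff some single same-strand annotated
#' transcript covers at least `dedup_overlap` of the novel unit's
#' length; survivors are appended to the annotated set. Annotated
#' entries are never modified.
#'
#' @param novel,annotated [transcript_set()]s.
#' @param dedup_overlap Fraction of the novel unit's length that must be
#'   covered for it to count as a duplicate (0 < f <= 1; default 0.5).
#' @return The unified [transcript_set()].
#' @export
merge_with_annotation <- function(novel, annotated, dedup_overlap = 0.5) {
  if (dedup_overlap <= 0 || dedup_overlap > 1)
    stop("dedup_overlap must be in (0, 1]")
  validate_transcripts(novel); validate_transcripts(annotated)
  if (nrow(novel) == 0L) return(annotated)
  if (any(novel$id %in% annotated$id))
    stop("duplicate ids across novel and annotated sets: ",
         paste(intersect(novel$id, annotated$id), collapse = ", "))
  drop <- rep(FALSE, nrow(novel))
  if (nrow(annotated)) {
    hits <- GenomicRanges::findOverlaps(tx_granges(novel),
                                        tx_granges(annotated),
                                        ignore.strand = FALSE)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    if (length(qi)) {
      ov <- pmin(novel$end[qi], annotated$end[si]) -
            pmax(novel$start[qi], annotated$start[si])
      frac <- ov / (novel$end[qi] - novel$start[qi])
      drop[unique(qi[frac >= dedup_overlap])] <- TRUE
    }
  }
  survivors <- novel[!drop, , drop = FALSE]
  out <- rbind(annotated, survivors)
  class(out) <- c("transcript_set", "data.frame")
  rownames(out) <- NULL
  out
}
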