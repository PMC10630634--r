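#' @importFrom stats coef complete.cases cor.test lm median optimize
#'   p.adjust pchisq pt quantile rnbinom rnorm rpois runif sd setNames
#'   t.test var
#' @importFrom utils head read.delim write.table
NULL

VALID_STRANDS <- c("+", "-")

#' Construct a genomic interval table
#'
#' Intervals are stored 0-based half-open (BED convention) on a named
#' chromosome with a mandatory strand. This is the coordinate currency of
#' the whole package; GTF input/output converts at the boundary.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector, 0-based inclusive start positions.
#' @param end Integer vector, 0-based exclusive end positions.
#' @param strand Character vector, each element `"+"` or `"-"`.
#' @return A data.frame with columns `chrom`, `start`, `end`, `strand`.
#' @export
genomic_interval <- function(chrom, start, end, strand) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df, what = "interval") {
  if (any(is.na(df$start)) || any(is.na(df$end)))
    stop(what, ": start/end must be finite")
  if (any(df$start < 0))
    stop(what, ": start must be >= 0")
  if (any(df$end <= df$start))
    stop(what, ": end must be > start (0-based half-open, length >= 1)")
  if (any(df$start != floor(df$start)) || any(df$end != floor(df$end)))
    stop(what, ": coordinates must be integral")
  bad <- !df$strand %in% VALID_STRANDS
  if (any(bad))
    stop(what, ": strand must be '+' or '-' (got '",
         df$strand[which(bad)[1]], "')")
  invisible(df)
}

#' Construct a transcript set
#'
#' A transcript set holds one row per transcript (interval plus id,
#' biotype and provenance) and a list-column of exons. Unspliced
#' transcripts carry exactly one exon spanning the whole interval, the
#' representation used for de novo transcription units.
#'
#' @param id Character vector of unique transcript ids.
#' @param chrom,start,end,strand Interval columns (0-based half-open).
#' @param biotype One of `"coding"`, `"lncRNA"`, `"antisense"`, `"novel"`.
#' @param source One of `"annotated"`, `"denovo"`.
#' @param exons Optional list of per-transcript exon data.frames with
#'   columns `start`, `end` (same chrom/strand as the transcript). When
#'   `NULL`, every transcript gets a single exon spanning its interval.
#' @param gene_id Optional character vector of gene ids (defaults to
#'   `id`).
#' @return A data.frame of class `transcript_set`.
#' @export
transcript_set <- function(id, chrom, start, end, strand,
                           biotype = "coding", source = "annotated",
                           exons = NULL, gene_id = NULL) {
  n <- length(id)
  df <- data.frame(id = as.character(id),
                   chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   strand = as.character(strand),
                   biotype = rep_len(as.character(biotype), n),
                   source = rep_len(as.character(source), n),
                   stringsAsFactors = FALSE)
  df$gene_id <- if (is.null(gene_id)) df$id else as.character(gene_id)
  if (is.null(exons)) {
    exons <- mapply(function(s, e) data.frame(start = s, end = e),
                    df$start, df$end, SIMPLIFY = FALSE)
  }
  df$exons <- exons
  class(df) <- c("transcript_set", "data.frame")
  validate_transcripts(df)
  df
}

validate_transcripts <- function(tx) {
  if (nrow(tx) == 0L) return(invisible(tx))
  if (anyDuplicated(tx$id))
    stop("transcript ids must be unique (duplicated: '",
         tx$id[duplicated(tx$id)][1], "')")
  validate_intervals(tx, "transcript")
  ok_bio <- c("coding", "lncRNA", "antisense", "novel")
  if (any(!tx$biotype %in% ok_bio))
    stop("biotype must be one of ", paste(ok_bio, collapse = ", "))
  if (any(!tx$source %in% c("annotated", "denovo")))
    stop("source must be 'annotated' or 'denovo'")
  for (i in seq_len(nrow(tx))) {
    ex <- tx$exons[[i]]
    if (!is.data.frame(ex) || nrow(ex) == 0L)
      stop("transcript '", tx$id[i], "': needs at least one exon")
    if (is.unsorted(ex$start, strictly = TRUE) && nrow(ex) > 1L)
      stop("transcript '", tx$id[i], "': exons must be sorted by start")
    if (any(ex$end <= ex$start))
      stop("transcript '", tx$id[i], "': exon end must exceed start")
    if (nrow(ex) > 1L && any(ex$start[-1] < ex$end[-nrow(ex)]))
      stop("transcript '", tx$id[i], "': exons must not overlap")
    if (ex$start[1] < tx$start[i] || ex$end[nrow(ex)] > tx$end[i])
      stop("transcript '", tx$id[i], "': exons outside interval")
  }
  invisible(tx)
}

#' Transcript lengths in bp
#' @param tx A `transcript_set`.
#' @param mode `"gene"` for interval length, `"exon"` for summed exon
#'   length.
#' @return Numeric vector named by transcript id.
#' @export
transcript_lengths <- function(tx, mode = c("gene", "exon")) {
  mode <- match.arg(mode)
  len <- if (mode == "gene") tx$end - tx$start
         else vapply(tx$exons, function(e) sum(e$end - e$start), 0)
  setNames(len, tx$id)
}

tx_granges <- function(tx) {
  GenomicRanges::GRanges(tx$chrom,
                         IRanges::IRanges(tx$start + 1, tx$end),
                         strand = tx$strand, id = tx$id)
}

#' Construct a strand-specific coverage track
#'
#' A run-length representation of read depth: non-overlapping, sorted
#' runs of constant depth; every position not covered by a run has
#' depth 0. Tracks are strand-separated by construction, mirroring
#' strand-resolved nascent-RNA protocols.
#'
#' @param chrom,start,end Run coordinates, 0-based half-open.
#' @param depth Non-negative depth (reads/bp) per run.
#' @param strand `"+"` or `"-"`; the strand of the whole track.
#' @return A data.frame of class `coverage_track` with attribute
#'   `strand`.
#' @export
coverage_track <- function(chrom = character(), start = numeric(),
                           end = numeric(), depth = numeric(),
                           strand = "+") {
  if (!is.character(strand) || length(strand) != 1L ||
      !strand %in% VALID_STRANDS)
    stop("track strand must be exactly '+' or '-'")
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), depth = as.numeric(depth),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$depth < 0)) stop("coverage depth must be >= 0")
    if (any(df$end <= df$start)) stop("coverage run end must exceed start")
    if (any(df$start < 0)) stop("coverage run start must be >= 0")
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    rownames(df) <- NULL
    by_chr <- split(df, df$chrom)
    for (runs in by_chr) {
      if (nrow(runs) > 1L && any(runs$start[-1] < runs$end[-nrow(runs)]))
        stop("coverage runs overlap on ", runs$chrom[1])
    }
  }
  attr(df, "strand") <- strand
  class(df) <- c("coverage_track", "data.frame")
  df
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track (", attr(x, "strand"), " strand): ",
      nrow(x), " runs on ", length(unique(x$chrom)),
      " chromosome(s)\n", sep = "")
  print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

track_strand <- function(track) attr(track, "strand")

#' Construct a count matrix with design metadata
#'
#' @param counts Integer matrix, features x samples, with dimnames.
#' @param groups Named character vector mapping every sample (column) to
#'   its condition label.
#' @return A list of class `count_matrix` with elements `counts` and
#'   `groups`.
#' @export
count_matrix <- function(counts, groups) {
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      is.null(colnames(counts)))
    stop("counts must carry feature rownames and sample colnames")
  storage.mode(counts) <- "double"
  if (anyDuplicated(rownames(counts))) stop("feature ids must be unique")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != floor(counts))) stop("counts must be integral")
  groups <- groups[colnames(counts)]
  if (any(is.na(groups)))
    stop("every sample needs a group label; missing for: ",
         paste(colnames(counts)[is.na(groups)], collapse = ", "))
  groups <- as.character(groups)
  names(groups) <- colnames(counts)
  structure(list(counts = counts, groups = groups),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix: ", nrow(x$counts), " features x ",
      ncol(x$counts), " samples; groups: ",
      paste(sprintf("%s(%d)", names(table(x$groups)), table(x$groups)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Sample-to-group map of a count matrix
#' @param cm A [count_matrix()].
#' @return Named character vector (names = sample ids).
#' @export
cm_groups <- function(cm) setNames(cm$groups, colnames(cm$counts))
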