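# Readers/writers for GTF, BED6/BED12, bedGraph and TSV tables.
# Parsing of the standard formats is delegated to rtracklayer; these
# wrappers enforce the package's coordinate convention (0-based
# half-open internally, conversion at the boundary) and its validation
# rules (mandatory strand, non-overlapping coverage runs).

check_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  nf <- lengths(strsplit(lines[keep], "\t", fixed = TRUE))
  if (any(nf != 9L)) {
    bad <- which(keep)[which(nf != 9L)[1]]
    stop("malformed GTF line ", bad, " in '", path,
         "': expected 9 tab-separated columns, found ", nf[nf != 9L][1])
  }
  invisible(sum(keep))
}

#' Read transcripts from a GTF file
#'
#' Parses an Ensembl/GENCODE-dialect GTF and aggregates exon records
#' into one transcript per `transcript_id`. GTF 1-based inclusive
#' coordinates are converted to the package's 0-based half-open
#' convention. Records without strand information are rejected:
#' strandedness is essential to every downstream step.
#'
#' @param path Path to a GTF file.
#' @return A [transcript_set()].
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  n_rec <- check_gtf_lines(path)
  if (n_rec == 0L)
    return(transcript_set(character(), character(), numeric(),
                          numeric(), character()))
  gr <- rtracklayer::import(path, format = "gtf")
  if (is.null(gr$transcript_id))
    stop("GTF attributes must contain transcript_id: ", path)
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0L) ex <- gr[gr$type == "transcript"]
  if (length(ex) == 0L) ex <- gr
  strand <- as.character(GenomicRanges::strand(ex))
  if (any(strand == "*"))
    stop("GTF record without strand: unstranded transcripts are not ",
         "supported")
  exdf <- data.frame(tid = ex$transcript_id,
                     chrom = as.character(GenomicRanges::seqnames(ex)),
                     start = GenomicRanges::start(ex) - 1,
                     end = as.numeric(GenomicRanges::end(ex)),
                     strand = strand,
                     gene_id = if (is.null(ex$gene_id)) ex$transcript_id
                               else ex$gene_id,
                     stringsAsFactors = FALSE)
  if (any(exdf$end <= exdf$start))
    stop("GTF record with end < start after coordinate conversion")
  biotype <- rep("coding", length(ex))
  for (col in c("transcript_biotype", "transcript_type", "gene_biotype",
                "gene_type")) {
    if (!is.null(S4Vectors::mcols(ex)[[col]])) {
      bt <- S4Vectors::mcols(ex)[[col]]
      biotype <- ifelse(bt %in% c("coding", "lncRNA", "antisense",
                                  "novel"), bt,
                 ifelse(bt == "protein_coding", "coding",
                 ifelse(grepl("antisense", bt), "antisense",
                 ifelse(grepl("lincRNA|lncRNA", bt), "lncRNA", "coding"))))
      break
    }
  }
  exdf$biotype <- biotype
  ord <- order(exdf$tid, exdf$start)
  exdf <- exdf[ord, , drop = FALSE]
  per <- split(exdf, exdf$tid)
  ids <- names(per)
  transcript_set(
    id = ids,
    chrom = vapply(per, function(d) d$chrom[1], ""),
    start = vapply(per, function(d) min(d$start), 0),
    end = vapply(per, function(d) max(d$end), 0),
    strand = vapply(per, function(d) d$strand[1], ""),
    biotype = vapply(per, function(d) d$biotype[1], ""),
    source = "annotated",
    exons = lapply(per, function(d)
      data.frame(start = d$start, end = d$end)),
    gene_id = vapply(per, function(d) d$gene_id[1], ""))
}

#' Write transcripts to a GTF file
#'
#' Emits one `transcript` record plus one `exon` record per exon, with
#' coordinates converted back to GTF's 1-based inclusive convention.
#'
#' @param tx A [transcript_set()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gtf <- function(tx, path) {
  validate_transcripts(tx)
  esc <- function(x) gsub("\"", "", x)
  lines <- character(0)
  if (nrow(tx)) {
    ord <- order(tx$chrom, tx$start, tx$id)
    for (i in ord) {
      attrs <- sprintf("gene_id \"%s\"; transcript_id \"%s\"; biotype \"%s\"; source_tag \"%s\";",
                       esc(tx$gene_id[i]), esc(tx$id[i]),
                       tx$biotype[i], tx$source[i])
      fmt1 <- function(x) format(x, scientific = FALSE, trim = TRUE)
      lines <- c(lines, sprintf("%s\tnascentr\ttranscript\t%s\t%s\t.\t%s\t.\t%s",
                                tx$chrom[i], fmt1(tx$start[i] + 1),
                                fmt1(tx$end[i]), tx$strand[i], attrs))
      ex <- tx$exons[[i]]
      lines <- c(lines, sprintf("%s\tnascentr\texon\t%s\t%s\t.\t%s\t.\t%s",
                                tx$chrom[i], fmt1(ex$start + 1),
                                fmt1(ex$end), tx$strand[i], attrs))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a strand-specific bedGraph coverage file
#'
#' @param path Path to a 4-column bedGraph (0-based half-open).
#' @param strand Strand label for the whole track, `"+"` or `"-"`
#'   (tracks must be strand-separated files).
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, strand) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!any(nzchar(trimws(readLines(path, warn = FALSE)))))
    return(coverage_track(strand = strand))
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) && any(gr$score < 0))
    stop("negative depth in bedGraph: ", path)
  coverage_track(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr) - 1,
                 as.numeric(GenomicRanges::end(gr)),
                 as.numeric(gr$score), strand = strand)
}

#' Write a coverage track as bedGraph
#' @param track A [coverage_track()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path) {
  df <- as.data.frame(track)[, c("chrom", "start", "end", "depth")]
  write.table(format(df, scientific = FALSE, trim = TRUE), path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

tx_bed_granges <- function(tx) {
  gr <- tx_granges(tx)
  gr$name <- tx$id
  blocks <- lapply(seq_len(nrow(tx)), function(i) {
    ex <- tx$exons[[i]]
    IRanges::IRanges(ex$start - tx$start[i] + 1, ex$end - tx$start[i])
  })
  gr$blocks <- methods::as(blocks, "IRangesList")
  gr
}

#' Write transcripts to a BED file
#'
#' Single-exon transcripts are written as BED6; multi-exon transcripts
#' as BED12 with exon blocks. Output is deterministically ordered by
#' (chrom, start, id).
#'
#' @param tx A [transcript_set()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(tx, path) {
  validate_transcripts(tx)
  if (nrow(tx) == 0L) { writeLines(character(0), path); return(invisible(path)) }
  tx <- tx[order(tx$chrom, tx$start, tx$id), , drop = FALSE]
  multi <- any(vapply(tx$exons, nrow, 0L) > 1L)
  gr <- tx_bed_granges(tx)
  if (!multi) gr$blocks <- NULL
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read transcripts from a BED file
#'
#' @param path Path to a BED6 or BED12 file.
#' @param source,biotype Provenance labels for the resulting set.
#' @return A [transcript_set()].
#' @export
read_bed <- function(path, source = "annotated", biotype = "novel") {
  if (!any(nzchar(trimws(readLines(path, warn = FALSE)))))
    return(transcript_set(character(), character(), numeric(),
                          numeric(), character()))
  gr <- rtracklayer::import(path, format = "bed")
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*"))
    stop("BED record without strand: unstranded records are not supported")
  start0 <- GenomicRanges::start(gr) - 1
  exons <- if (!is.null(gr$blocks)) {
    lapply(seq_along(gr), function(i) {
      b <- gr$blocks[[i]]
      data.frame(start = start0[i] + IRanges::start(b) - 1,
                 end = start0[i] + IRanges::end(b))
    })
  } else NULL
  transcript_set(gr$name, as.character(GenomicRanges::seqnames(gr)),
                 start0, as.numeric(GenomicRanges::end(gr)), strand,
                 biotype = biotype, source = source, exons = exons)
}

#' Read a feature x sample count matrix from TSV
#'
#' Expects a header row of sample ids, first column of feature ids, and
#' a two-column design table (`sample`, `group`).
#'
#' @param counts_path Path to the counts TSV.
#' @param design_path Path to the design TSV.
#' @return A [count_matrix()].
#' @export
read_counts <- function(counts_path, design_path) {
  tab <- read.delim(counts_path, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  des <- read.delim(design_path, check.names = FALSE)
  if (!all(c("sample", "group") %in% names(des)))
    stop("design TSV needs columns 'sample' and 'group'")
  count_matrix(m, setNames(as.character(des$group),
                           as.character(des$sample)))
}

#' Write a count matrix (and its design) to TSV
#' @param cm A [count_matrix()].
#' @param counts_path,design_path Output paths; `design_path = NULL`
#'   skips the design file.
#' @return Invisibly, `counts_path`.
#' @export
write_counts <- function(cm, counts_path, design_path = NULL) {
  df <- data.frame(feature = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(design_path))
    write.table(data.frame(sample = names(cm_groups(cm)),
                           group = cm$groups),
                design_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(counts_path)
}
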