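# Strand-aware sense-antisense pairing, pair-level fold-change
# correlation, ASRG/NARG classification, and promoter HRE scanning.

pair_topology <- function(ps, pe, ms, me) {
  # plus unit transcribes left->right (TSS = ps), minus right->left
  # (TSS = me); convergent = 3' ends overlap, divergent = 5' ends.
  if ((ps <= ms && pe >= me) || (ms <= ps && me >= pe)) return("nested")
  if (ps < ms && pe < me) return("convergent")
  if (ms < ps && me < pe) return("divergent")
  "other"
}

#' Find sense-antisense transcript pairs
#'
#' For every (coding gene, opposite-strand transcript) pair with
#' genomic overlap, computes the shared bp on the gene-body intervals
#' (TSS to TTS, not exon unions: nascent transcription covers introns)
#' and retains the pair iff the overlap covers at least `min_fraction`
#' of the antisense transcript's length (inclusive). Topology labels
#' the relative orientation: `convergent` (3' ends overlap),
#' `divergent` (5' ends overlap), `nested` (one inside the other).
#'
#' @param transcripts Candidate antisense partners, a
#'   [transcript_set()] (any biotype; same-strand entries are simply
#'   never paired).
#' @param coding_genes The sense genes, a [transcript_set()].
#' @param min_fraction Minimum overlap as a fraction of the antisense
#'   length (default 0.10).
#' @return A data.frame of class `sa_pairs`: `sense_id`,
#'   `antisense_id`, `overlap_bp`, `overlap_fraction`, `topology`.
#' @export
find_antisense_pairs <- function(transcripts, coding_genes,
                                 min_fraction = 0.10) {
  validate_transcripts(transcripts); validate_transcripts(coding_genes)
  empty <- data.frame(sense_id = character(), antisense_id = character(),
                      overlap_bp = numeric(),
                      overlap_fraction = numeric(),
                      topology = character(), stringsAsFactors = FALSE)
  class(empty) <- c("sa_pairs", "data.frame")
  if (nrow(transcripts) == 0L || nrow(coding_genes) == 0L) return(empty)
  hits <- GenomicRanges::findOverlaps(tx_granges(coding_genes),
                                      tx_granges(transcripts),
                                      ignore.strand = TRUE)
  gi <- S4Vectors::queryHits(hits); ti <- S4Vectors::subjectHits(hits)
  opp <- coding_genes$strand[gi] != transcripts$strand[ti]
  gi <- gi[opp]; ti <- ti[opp]
  if (length(gi) == 0L) return(empty)
  ov <- pmin(coding_genes$end[gi], transcripts$end[ti]) -
        pmax(coding_genes$start[gi], transcripts$start[ti])
  as_len <- transcripts$end[ti] - transcripts$start[ti]
  frac <- ov / as_len
  keep <- frac >= min_fraction
  gi <- gi[keep]; ti <- ti[keep]; ov <- ov[keep]; frac <- frac[keep]
  if (length(gi) == 0L) return(empty)
  topo <- vapply(seq_along(gi), function(k) {
    if (coding_genes$strand[gi[k]] == "+")
      pair_topology(coding_genes$start[gi[k]], coding_genes$end[gi[k]],
                    transcripts$start[ti[k]], transcripts$end[ti[k]])
    else
      pair_topology(transcripts$start[ti[k]], transcripts$end[ti[k]],
                    coding_genes$start[gi[k]], coding_genes$end[gi[k]])
  }, "")
  out <- data.frame(sense_id = coding_genes$id[gi],
                    antisense_id = transcripts$id[ti],
                    overlap_bp = ov, overlap_fraction = frac,
                    topology = topo, stringsAsFactors = FALSE)
  out <- out[order(out$sense_id, out$antisense_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sa_pairs", "data.frame")
  out
}

de_lookup <- function(de_table, ids, col, what) {
  i <- match(ids, de_table$feature)
  if (anyNA(i))
    stop(what, " member(s) missing from DE table: ",
         paste(unique(ids[is.na(i)]), collapse = ", "))
  de_table[[col]][i]
}

#' Correlate sense and antisense fold changes across pairs
#'
#' Pearson correlation between sense log2FC and antisense log2FC, one
#' observation per pair; two-sided p from the t transform of r.
#'
#' @param pairs An `sa_pairs` table.
#' @param de_table A `de_result` (needs `feature` and `log2FC`).
#' @return A list with `n_pairs`, `pearson_r`, `p_value`.
#' @export
correlate_pairs <- function(pairs, de_table) {
  if (nrow(pairs) < 3L) stop("need at least 3 pairs for a correlation")
  x <- de_lookup(de_table, pairs$sense_id, "log2FC", "sense")
  y <- de_lookup(de_table, pairs$antisense_id, "log2FC", "antisense")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite log2FC among paired features")
  ct <- cor.test(x, y, method = "pearson")
  list(n_pairs = nrow(pairs), pearson_r = unname(ct$estimate),
       p_value = ct$p.value)
}

#' Classify sense-antisense regulation (ASRG / NARG)
#'
#' With `mode = "both_de"` (default): a pair is an antisense-regulated
#' gene (ASRG) iff both members are differentially expressed with
#' opposite-sign log2FC; a non-antisense-regulated gene (NARG) iff both
#' are DE with same-sign log2FC; otherwise `not_regulated`. With
#' `mode = "directional"`, one DE member suffices provided the two fold
#' changes have the stated sign relation.
#'
#' @param pairs An `sa_pairs` table.
#' @param de_table A classified `de_result` (needs `feature`, `log2FC`,
#'   `status`).
#' @param mode `"both_de"` or `"directional"`.
#' @return `pairs` with a `regulation_class` column.
#' @export
classify_regulation <- function(pairs, de_table,
                                mode = c("both_de", "directional")) {
  mode <- match.arg(mode)
  if (nrow(pairs) == 0L) {
    pairs$regulation_class <- character(0)
    return(pairs)
  }
  s_st <- de_lookup(de_table, pairs$sense_id, "status", "sense")
  a_st <- de_lookup(de_table, pairs$antisense_id, "status", "antisense")
  s_fc <- de_lookup(de_table, pairs$sense_id, "log2FC", "sense")
  a_fc <- de_lookup(de_table, pairs$antisense_id, "log2FC", "antisense")
  s_de <- s_st != "not_DE"; a_de <- a_st != "not_DE"
  opposite <- sign(s_fc) * sign(a_fc) < 0
  cls <- if (mode == "both_de") {
    ifelse(s_de & a_de & opposite, "ASRG",
    ifelse(s_de & a_de & !opposite, "NARG", "not_regulated"))
  } else {
    ifelse((s_de | a_de) & opposite, "ASRG",
    ifelse((s_de | a_de) & !opposite, "NARG", "not_regulated"))
  }
  pairs$regulation_class <- cls
  pairs
}

REVCOMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

reverse_complement <- function(seq) {
  paste(rev(REVCOMP[strsplit(seq, "")[[1]]]), collapse = "")
}

#' Scan a promoter sequence for hypoxia response elements
#'
#' Finds every occurrence of the HRE core consensus RCGTG (R = A or G)
#' on both strands; minus-strand hits are located through the reverse
#' complement. `N` bases never match. Overlapping occurrences are all
#' reported.
#'
#' @param sequence DNA string over `A`, `C`, `G`, `T`, `N`
#'   (case-insensitive).
#' @param offset Genomic position of the first base of `sequence`
#'   (reported positions are `offset` + 0-based position in the
#'   sequence).
#' @return A data.frame with `position` (0-based start of the 5-mer on
#'   the plus strand), `strand`, `match` (the plus-strand 5-mer at that
#'   position).
#' @export
scan_hre <- function(sequence, offset = 0) {
  seq <- toupper(sequence)
  if (grepl("[^ACGTN]", seq))
    stop("sequence contains characters outside {A,C,G,T,N}")
  hits_at <- function(s) {
    m <- gregexpr("(?=[AG]CGTG)", s, perl = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m) - 1L
  }
  L <- nchar(seq)
  plus <- hits_at(seq)
  rc_hits <- hits_at(reverse_complement(seq))
  minus <- sort(L - rc_hits - 5L)
  pos <- c(plus, minus)
  strand <- c(rep("+", length(plus)), rep("-", length(minus)))
  ord <- order(pos, strand)
  data.frame(position = pos[ord] + offset, strand = strand[ord],
             match = vapply(pos[ord], function(p)
               substr(seq, p + 1, p + 5), ""),
             stringsAsFactors = FALSE)
}
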