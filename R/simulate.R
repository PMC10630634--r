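# Seeded generators for every input the analysis consumes: a toy
# genome with convergent antisense architecture, strand-specific
# coverage with promoter-proximal pausing, NB counts with planted
# effects (including inverse sense-antisense pairs), labeling time
# courses and qPCR CT tables -- each with a ground-truth manifest.
# Every generator is bit-reproducible from (seed, params).

#' Generate a toy genome with antisense architecture
#'
#' Places non-overlapping plus-strand coding genes (lengths log-uniform
#' 2-60 kb) along one chromosome; a chosen fraction receive one
#' convergent minus-strand antisense unit whose overlap fraction (of
#' the antisense length) is drawn uniformly from `overlap_range`. The
#' antisense unit stays within its host gene's territory, so each one
#' overlaps exactly its host.
#'
#' @param n_genes Number of coding genes.
#' @param antisense_fraction Fraction of genes given an antisense unit.
#' @param overlap_range Length-2 numeric in (0, 1]; range of antisense
#'   overlap fractions.
#' @param seed Integer seed.
#' @param chrom Chromosome name.
#' @return A list: `transcripts` ([transcript_set()] of genes then
#'   antisense units), `chrom_sizes` (named vector), `pairs`
#'   (data.frame of planted host/antisense pairs with their drawn
#'   overlap fraction).
#' @export
make_toy_genome <- function(n_genes, antisense_fraction = 0.1,
                            overlap_range = c(0.1, 0.9), seed = 1,
                            chrom = "chrS") {
  if (n_genes < 0) stop("n_genes must be >= 0")
  if (antisense_fraction < 0 || antisense_fraction > 1)
    stop("antisense_fraction must be in [0, 1]")
  if (any(overlap_range <= 0) || any(overlap_range > 1))
    stop("overlap_range must lie in (0, 1]")
  empty_pairs <- data.frame(sense_id = character(),
                            antisense_id = character(),
                            overlap_fraction = numeric(),
                            stringsAsFactors = FALSE)
  if (n_genes == 0L)
    return(list(transcripts = transcript_set(character(), character(),
                                             numeric(), numeric(),
                                             character()),
                chrom_sizes = setNames(10000, chrom),
                pairs = empty_pairs))
  set.seed(seed)
  gaps <- round(runif(n_genes, 5000, 20000))
  lens <- round(exp(runif(n_genes, log(2000), log(60000))))
  starts <- cumsum(gaps) + cumsum(c(0, lens[-n_genes]))
  ends <- starts + lens
  ids <- sprintf("G%05d", seq_len(n_genes))
  n_as <- round(antisense_fraction * n_genes)
  as_hosts <- if (n_as > 0) sort(sample.int(n_genes, n_as)) else integer(0)
  as_rows <- list()
  pairs <- empty_pairs
  for (k in seq_along(as_hosts)) {
    i <- as_hosts[k]
    f <- runif(1, overlap_range[1], overlap_range[2])
    gap_after <- if (i < n_genes) starts[i + 1] - ends[i] else 10000
    max_len <- floor(min(lens[i] / f,
                         if (f < 1) (gap_after - 100) / (1 - f) else Inf,
                         20000))
    min_len <- max(500, ceiling(1 / f))
    if (max_len < min_len) next
    as_len <- round(runif(1, min_len, max_len))
    ov <- max(1, round(f * as_len))
    as_start <- ends[i] - ov
    as_rows[[k]] <- data.frame(id = paste0("AS_", ids[i]),
                               start = as_start, end = as_start + as_len,
                               host = ids[i],
                               frac = ov / as_len,
                               stringsAsFactors = FALSE)
  }
  as_df <- if (length(as_rows)) do.call(rbind, as_rows) else NULL
  tx <- transcript_set(
    id = c(ids, if (!is.null(as_df)) as_df$id),
    chrom = chrom,
    start = c(starts, if (!is.null(as_df)) as_df$start),
    end = c(ends, if (!is.null(as_df)) as_df$end),
    strand = c(rep("+", n_genes),
               if (!is.null(as_df)) rep("-", nrow(as_df))),
    biotype = c(rep("coding", n_genes),
                if (!is.null(as_df)) rep("antisense", nrow(as_df))))
  if (!is.null(as_df))
    pairs <- data.frame(sense_id = as_df$host, antisense_id = as_df$id,
                        overlap_fraction = as_df$frac,
                        stringsAsFactors = FALSE)
  list(transcripts = tx,
       chrom_sizes = setNames(max(tx$end) + 10000, chrom),
       pairs = pairs)
}

rle_to_runs <- function(values, offset, chrom) {
  r <- rle(values)
  ends <- offset + cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values > 0
  data.frame(chrom = rep(chrom, sum(keep)), start = starts[keep],
             end = ends[keep], depth = r$values[keep])
}

#' Simulate strand-specific coverage with promoter pausing
#'
#' Gene-body depth is Poisson-jittered per bp around the transcript's
#' expression level (reads/bp); the first `pause_window` bp downstream
#' of the TSS get their mean multiplied by the gene's pausing ratio. A
#' constant background of `noise_depth` covers the whole genome on
#' both strands.
#'
#' @param annotation A [transcript_set()] (same-strand entries must not
#'   overlap).
#' @param expression Named vector of body depth levels (reads/bp) per
#'   transcript id; missing ids get 0.
#' @param pausing_ratio Scalar or named per-transcript ratio (>= 1).
#' @param noise_depth Constant background depth added everywhere.
#' @param chrom_sizes Named vector of chromosome sizes.
#' @param seed Integer seed.
#' @param pause_window Width of the paused window in bp (default 300).
#' @return A list with `plus` and `minus` [coverage_track()]s.
#' @export
simulate_coverage <- function(annotation, expression, pausing_ratio = 1,
                              noise_depth = 0, chrom_sizes, seed = 1,
                              pause_window = 300) {
  validate_transcripts(annotation)
  if (any(pausing_ratio < 1)) stop("pausing_ratio must be >= 1")
  if (noise_depth < 0) stop("noise_depth must be >= 0")
  set.seed(seed)
  expr <- setNames(rep(0, nrow(annotation)), annotation$id)
  expr[names(expression)] <- expression
  pr <- setNames(rep_len(pausing_ratio, nrow(annotation)), annotation$id)
  if (!is.null(names(pausing_ratio))) {
    pr[] <- 1
    pr[names(pausing_ratio)] <- pausing_ratio
  }
  one_strand <- function(strand) {
    sel <- annotation[annotation$strand == strand, , drop = FALSE]
    sel <- sel[order(sel$chrom, sel$start), , drop = FALSE]
    runs <- list()
    for (chrom in names(chrom_sizes)) {
      g <- sel[sel$chrom == chrom, , drop = FALSE]
      cursor <- 0
      for (i in seq_len(nrow(g))) {
        if (noise_depth > 0 && g$start[i] > cursor)
          runs[[length(runs) + 1L]] <-
            data.frame(chrom = chrom, start = cursor, end = g$start[i],
                       depth = noise_depth)
        len <- g$end[i] - g$start[i]
        lam <- rep(expr[g$id[i]], len)
        w <- min(pause_window, len)
        if (strand == "+") lam[seq_len(w)] <- lam[seq_len(w)] * pr[g$id[i]]
        else lam[(len - w + 1):len] <- lam[(len - w + 1):len] * pr[g$id[i]]
        depth <- if (expr[g$id[i]] > 0) rpois(len, lam) else rep(0L, len)
        runs[[length(runs) + 1L]] <-
          rle_to_runs(depth + noise_depth, g$start[i], chrom)
        cursor <- g$end[i]
      }
      if (noise_depth > 0 && cursor < chrom_sizes[[chrom]])
        runs[[length(runs) + 1L]] <-
          data.frame(chrom = chrom, start = cursor,
                     end = chrom_sizes[[chrom]], depth = noise_depth)
    }
    df <- if (length(runs)) do.call(rbind, runs)
          else data.frame(chrom = character(), start = numeric(),
                          end = numeric(), depth = numeric())
    coverage_track(df$chrom, df$start, df$end, df$depth, strand = strand)
  }
  list(plus = one_strand("+"), minus = one_strand("-"))
}

#' Simulate NB counts with planted effects and inverse pairs
#'
#' Counts are drawn NB with mean
#' `baseline * 2^(log2FC * condition) * library-size factor` and
#' variance `mu + phi * mu^2`. Selected sense-antisense pairs are
#' planted as inversely regulated: antisense log2FC drawn from
#' `inverse_up`, sense log2FC from `-inverse_down`. A truth manifest
#' records every planted value.
#'
#' @param annotation A [transcript_set()]; one feature per transcript.
#' @param pairs Host/antisense pair table from [make_toy_genome()]
#'   (required when `n_inverse_pairs > 0`).
#' @param n_per_group Named integer vector, samples per group; the
#'   first group is the reference condition, the second the treated
#'   one.
#' @param baseline_means Named per-feature baseline means; `NULL` draws
#'   log-normal baselines (median 150).
#' @param planted_lfc Named log2FC vector for arbitrary features
#'   (unnamed features default to 0); pair planting overrides it.
#' @param n_inverse_pairs Number of pairs planted as inversely
#'   regulated.
#' @param inverse_up,inverse_down Ranges (log2) for antisense
#'   up-regulation and sense down-regulation of planted pairs.
#' @param phi NB dispersion (>= 0; 0 gives Poisson counts).
#' @param lib_size_factors Per-sample relative depth factors (default
#'   all 1).
#' @param seed Integer seed.
#' @return A list: `cm` ([count_matrix()]) and `truth` (manifest:
#'   `features`, `pairs`, `params`).
#' @export
simulate_counts <- function(annotation, pairs = NULL,
                            n_per_group = c(normoxia = 4, hypoxia = 4),
                            baseline_means = NULL, planted_lfc = NULL,
                            n_inverse_pairs = 0,
                            inverse_up = c(2, 4),
                            inverse_down = c(0.7, 2),
                            phi = 0.1, lib_size_factors = NULL,
                            seed = 1) {
  if (phi < 0) stop("phi must be >= 0")
  if (is.null(names(n_per_group)) || length(n_per_group) != 2L)
    stop("n_per_group must be a named length-2 vector")
  ids <- annotation$id
  set.seed(seed)
  base <- if (is.null(baseline_means)) {
    setNames(pmax(5, round(exp(rnorm(length(ids), log(150), 1)))), ids)
  } else {
    if (!all(ids %in% names(baseline_means)))
      stop("baseline_means must cover every feature")
    baseline_means[ids]
  }
  lfc <- setNames(rep(0, length(ids)), ids)
  if (!is.null(planted_lfc)) {
    if (!all(names(planted_lfc) %in% ids))
      stop("planted_lfc names outside annotation")
    lfc[names(planted_lfc)] <- planted_lfc
  }
  pair_truth <- data.frame(sense_id = character(),
                           antisense_id = character(),
                           class = character(), stringsAsFactors = FALSE)
  if (n_inverse_pairs > 0) {
    if (is.null(pairs) || nrow(pairs) < n_inverse_pairs)
      stop("n_inverse_pairs exceeds available pairs")
    sel <- sort(sample.int(nrow(pairs), n_inverse_pairs))
    sid <- pairs$sense_id[sel]; aid <- pairs$antisense_id[sel]
    lfc[aid] <- runif(n_inverse_pairs, inverse_up[1], inverse_up[2])
    lfc[sid] <- -runif(n_inverse_pairs, inverse_down[1], inverse_down[2])
    base[c(sid, aid)] <- pmax(base[c(sid, aid)], 100)
    pair_truth <- data.frame(sense_id = sid, antisense_id = aid,
                             class = "ASRG", stringsAsFactors = FALSE)
  }
  groups <- rep(names(n_per_group), n_per_group)
  n_s <- sum(n_per_group)
  samples <- paste0(groups, "_", unlist(lapply(n_per_group, seq_len)))
  if (is.null(lib_size_factors)) lib_size_factors <- rep(1, n_s)
  cond <- as.numeric(groups == names(n_per_group)[2])
  mu <- outer(base, rep(1, n_s)) *
        2^(outer(lfc, cond)) *
        matrix(lib_size_factors, length(ids), n_s, byrow = TRUE)
  counts <- if (phi == 0) {
    matrix(rpois(length(mu), mu), nrow(mu), ncol(mu))
  } else {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / phi),
           nrow(mu), ncol(mu))
  }
  dimnames(counts) <- list(ids, samples)
  truth <- list(
    features = data.frame(id = ids, baseline = unname(base),
                          log2FC = unname(lfc), de = lfc != 0,
                          stringsAsFactors = FALSE),
    pairs = pair_truth,
    params = list(seed = seed, phi = phi,
                  n_per_group = as.list(n_per_group),
                  inverse_up = inverse_up, inverse_down = inverse_down))
  list(cm = count_matrix(counts, setNames(groups, samples)),
       truth = truth)
}

#' Simulate a metabolic-labeling time course
#'
#' Labeled abundance grows linearly with labeling time at the true
#' synthesis rate, with multiplicative Gaussian noise, floored at 0.
#'
#' @param true_slope Abundance units per minute.
#' @param times Labeling durations in minutes (default 15/30/45/60).
#' @param sigma_frac Noise standard deviation as a fraction of signal.
#' @param replicates Replicates per time point.
#' @param seed Integer seed.
#' @return A data.frame with `time`, `replicate`, `abundance`, plus
#'   attribute `true_slope`.
#' @export
simulate_labeling <- function(true_slope, times = c(15, 30, 45, 60),
                              sigma_frac = 0.05, replicates = 3,
                              seed = 1) {
  if (sigma_frac < 0) stop("sigma_frac must be >= 0")
  set.seed(seed)
  grid <- expand.grid(replicate = seq_len(replicates), time = times)
  ab <- pmax(0, true_slope * grid$time *
                (1 + rnorm(nrow(grid), 0, sigma_frac)))
  out <- data.frame(time = grid$time, replicate = grid$replicate,
                    abundance = ab)
  attr(out, "true_slope") <- true_slope
  out
}

#' Simulate a qPCR CT table
#'
#' CT of the target decreases by log2(fold) relative to the base cycle;
#' the reference gene is stable. Both receive Gaussian cycle noise.
#'
#' @param fold_changes Named vector of true fold changes per group; the
#'   calibrator group should carry fold 1.
#' @param calibrator_group Name of the calibrator group (must be in
#'   `fold_changes`).
#' @param sigma_ct Cycle noise standard deviation.
#' @param replicates Replicates per group.
#' @param base_ct,ref_ct Baseline target and reference cycles.
#' @param seed Integer seed.
#' @return A data.frame usable by [ddct()] (`sample`, `group`,
#'   `target`, `ct_target`, `ct_reference`), with attribute
#'   `true_folds`.
#' @export
simulate_qpcr <- function(fold_changes, calibrator_group = names(fold_changes)[1],
                          sigma_ct = 0.15, replicates = 3,
                          base_ct = 25, ref_ct = 18, seed = 1) {
  if (sigma_ct < 0) stop("sigma_ct must be >= 0")
  if (!calibrator_group %in% names(fold_changes))
    stop("calibrator group must appear in fold_changes")
  set.seed(seed)
  groups <- rep(names(fold_changes), each = replicates)
  folds <- rep(unname(fold_changes), each = replicates)
  n <- length(groups)
  out <- data.frame(
    sample = paste0(groups, "_", rep(seq_len(replicates),
                                     length(fold_changes))),
    group = groups, target = "target",
    ct_target = base_ct - log2(folds) + rnorm(n, 0, sigma_ct),
    ct_reference = ref_ct + rnorm(n, 0, sigma_ct),
    stringsAsFactors = FALSE)
  attr(out, "true_folds") <- fold_changes
  out
}

#' Generate the default synthetic scene
#'
#' One seeded, canonical integration fixture: a 3000-gene toy genome
#' with 300 convergent antisense units; NB counts (phi = 0.1, 4 vs 4)
#' with 25 planted inverse sense-antisense pairs (antisense strongly
#' up, sense clearly down), 10 co-regulated (NARG-style) pairs, DE
#' planted on unpaired genes and on antisense units alone; a labeling
#' time course pair (slopes 1.91 vs 0.34); a qPCR table (fold 4); and
#' a strand-specific coverage panel over the first `coverage_genes`
#' loci with 5-fold promoter pausing. With `outdir`, all inputs are
#' written as plain-text files plus a `truth.json` manifest.
#'
#' @param seed Integer master seed (default 42); sub-generators derive
#'   fixed offsets from it.
#' @param n_genes,n_antisense,n_inverse_pairs Scene dimensions.
#' @param phi NB dispersion.
#' @param coverage_genes Number of leading loci in the coverage panel.
#' @param outdir Optional directory to write `toy.gtf`, `counts.tsv`,
#'   `design.tsv`, `labeling.tsv`, `ct.tsv`, coverage bedGraphs and
#'   `truth.json`.
#' @return A list: `genome`, `cm`, `truth`, `labeling` (list of two
#'   series), `ct`, `coverage`, `coverage_expression`.
#' @export
simulate_scene <- function(seed = 42, n_genes = 3000, n_antisense = 300,
                           n_inverse_pairs = 25, phi = 0.1,
                           coverage_genes = 50, outdir = NULL) {
  genome <- make_toy_genome(n_genes,
                            antisense_fraction = n_antisense / n_genes,
                            overlap_range = c(0.2, 0.9), seed = seed)
  tx <- genome$transcripts
  pairs <- genome$pairs
  # background effects: avoid accidental inverse pairs -- same-sign
  # pairs, antisense-only effects, and effects on unpaired genes
  set.seed(seed + 1)
  paired_genes <- pairs$sense_id
  unpaired <- setdiff(tx$id[tx$biotype == "coding"], paired_genes)
  n_bg <- min(150, floor(length(unpaired) / 2))
  bg_genes <- sample(unpaired, n_bg)
  bg_lfc <- setNames(sample(c(-1, 1), n_bg, TRUE) * runif(n_bg, 1, 3),
                     bg_genes)
  free_pairs <- seq_len(nrow(pairs))
  spare <- max(nrow(pairs) - n_inverse_pairs, 0)
  n_narg <- min(10, floor(spare / 2))
  narg_sel <- sample(free_pairs, n_narg)
  narg <- pairs[narg_sel, , drop = FALSE]
  narg_lfc <- setNames(rep(runif(n_narg, 1, 2.5), 2),
                       c(narg$sense_id, narg$antisense_id))
  n_as <- min(15, spare - n_narg)
  as_only <- sample(setdiff(free_pairs, narg_sel), n_as)
  as_lfc <- setNames(runif(n_as, 1, 3), pairs$antisense_id[as_only])
  planted <- c(bg_lfc, narg_lfc, as_lfc)
  inv_candidates <- pairs[setdiff(free_pairs, c(narg_sel, as_only)), ]
  sim <- simulate_counts(tx, pairs = inv_candidates,
                         n_per_group = c(normoxia = 4, hypoxia = 4),
                         planted_lfc = planted,
                         n_inverse_pairs = n_inverse_pairs,
                         inverse_up = c(2, 4), inverse_down = c(1.5, 2.5),
                         phi = phi, seed = seed + 2)
  sim$truth$pairs_background <- data.frame(
    sense_id = c(narg$sense_id, pairs$sense_id[as_only]),
    antisense_id = c(narg$antisense_id, pairs$antisense_id[as_only]),
    class = c(rep("NARG_planted", nrow(narg)),
              rep("antisense_only", length(as_only))),
    stringsAsFactors = FALSE)
  panel <- tx[seq_len(min(coverage_genes, nrow(tx))), , drop = FALSE]
  set.seed(seed + 3)
  cov_expr <- setNames(round(runif(nrow(panel), 5, 20)), panel$id)
  coverage <- simulate_coverage(panel, cov_expr, pausing_ratio = 5,
                                noise_depth = 1,
                                chrom_sizes = setNames(max(panel$end) + 1000,
                                                       panel$chrom[1]),
                                seed = seed + 4)
  lab_untreated <- simulate_labeling(1.91, seed = seed + 5)
  lab_treated <- simulate_labeling(0.34, seed = seed + 6)
  ct <- simulate_qpcr(c(normoxia = 1, hypoxia = 4), seed = seed + 7)
  truth <- sim$truth
  truth$params$scene <- list(seed = seed, n_genes = n_genes,
                             n_antisense = n_antisense,
                             n_inverse_pairs = n_inverse_pairs,
                             coverage_genes = coverage_genes,
                             coverage_pausing_ratio = 5,
                             labeling_slopes = c(1.91, 0.34),
                             qpcr_fold = 4)
  truth$coverage_expression <- as.list(cov_expr)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_gtf(tx, file.path(outdir, "toy.gtf"))
    write_counts(sim$cm, file.path(outdir, "counts.tsv"),
                 file.path(outdir, "design.tsv"))
    write_bedgraph(coverage$plus,
                   file.path(outdir, "coverage.plus.bedgraph"))
    write_bedgraph(coverage$minus,
                   file.path(outdir, "coverage.minus.bedgraph"))
    lab <- rbind(data.frame(condition = "untreated", lab_untreated),
                 data.frame(condition = "DMOG", lab_treated))
    write.table(lab, file.path(outdir, "labeling.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(ct, file.path(outdir, "ct.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(genome = genome, cm = sim$cm, truth = truth,
       labeling = list(untreated = lab_untreated, DMOG = lab_treated),
       ct = ct, coverage = coverage, coverage_expression = cov_expr)
}
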