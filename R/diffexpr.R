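# Self-contained negative-binomial differential expression:
# expression filter, TMM normalisation, dispersion estimation, NB GLM
# likelihood-ratio test, BH FDR and threshold-based DE calling.
# The NB model is parameterised by (mean mu, dispersion phi) with
# variance mu + phi * mu^2.

#' Filter weakly expressed features
#'
#' A feature is retained iff, in at least one condition group, more
#' than `min_prop` of that group's samples (>= as a fraction) have a
#' count strictly greater than `min_count`.
#'
#' @param cm A [count_matrix()].
#' @param min_count Count that must be exceeded (default 10).
#' @param min_prop Required fraction of samples within a group
#'   (default 0.70).
#' @return The filtered [count_matrix()].
#' @export
filter_expressed <- function(cm, min_count = 10, min_prop = 0.70) {
  if (nrow(cm$counts) == 0L) return(cm)
  keep <- rep(FALSE, nrow(cm$counts))
  for (g in unique(cm$groups)) {
    cols <- which(cm$groups == g)
    frac <- rowMeans(cm$counts[, cols, drop = FALSE] > min_count)
    keep <- keep | (frac >= min_prop)
  }
  count_matrix(cm$counts[keep, , drop = FALSE], cm_groups(cm))
}

#' Trimmed-mean-of-M-values normalisation factors
#'
#' Computes the classic TMM scaling factors: per sample against a
#' reference sample, gene-wise log ratios (M) and mean log abundances
#' (A) over genes nonzero in both samples are doubly trimmed (30% of
#' each M tail, 5% of each A tail) and the factor is 2 to the
#' precision-weighted mean of the surviving M values, with weights from
#' the asymptotic binomial (delta-method) variance. Factors are
#' rescaled to geometric mean 1. The reference is the sample whose
#' 75th-percentile count fraction is closest to the mean of those
#' fractions.
#'
#' @param cm A [count_matrix()].
#' @param logratio_trim,abundance_trim Tail-trim fractions for M and A.
#' @return A list of class `norm_factors` with `factors` (named, product
#'   1), `lib_sizes` (raw column sums), and `effective_lib_sizes`
#'   (`lib_sizes * factors`).
#' @export
tmm_factors <- function(cm, logratio_trim = 0.30, abundance_trim = 0.05) {
  y <- cm$counts
  lib <- colSums(y)
  if (any(lib == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(y)[lib == 0], collapse = ", "))
  f75 <- vapply(seq_len(ncol(y)),
                function(j) quantile(y[, j], 0.75) / lib[j], 0)
  ref <- which.min(abs(f75 - mean(f75)))
  one_factor <- function(j) {
    if (j == ref) return(1)
    obs <- y[, j] / lib[j]
    refp <- y[, ref] / lib[ref]
    ok <- obs > 0 & refp > 0
    if (!any(ok)) return(1)
    M <- log2(obs[ok] / refp[ok])
    A <- 0.5 * log2(obs[ok] * refp[ok])
    # asymptotic variance of M (delta method on binomial proportions)
    v <- (lib[j] - y[ok, j]) / (lib[j] * y[ok, j]) +
         (lib[ref] - y[ok, ref]) / (lib[ref] * y[ok, ref])
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * abundance_trim) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM &
            rank(A) >= loA & rank(A) <= hiA
    if (!any(keep)) return(1)
    2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
  }
  f <- vapply(seq_len(ncol(y)), one_factor, 0)
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(y)
  structure(list(factors = f, lib_sizes = lib,
                 effective_lib_sizes = lib * f),
            class = "norm_factors")
}

# Vectorised Newton fit of per-group NB means on the log scale.
# y: features x samples; s: effective library sizes; groups: list of
# column-index vectors; phi: scalar or per-feature dispersion.
# Returns list(mu = fitted matrix, m = per-group means per unit library
# size, converged = logical vector).
fit_group_means <- function(y, s, groups, phi, max_iter = 50,
                            tol = 1e-8) {
  nf <- nrow(y)
  phi <- rep_len(phi, nf)
  m <- matrix(0, nf, length(groups))
  converged <- rep(TRUE, nf)
  for (g in seq_along(groups)) {
    J <- groups[[g]]
    sg <- s[J]
    rs <- rowSums(y[, J, drop = FALSE])
    pos <- rs > 0
    mg <- rs / sum(sg)           # Poisson MLE; exact when phi = 0
    if (any(pos) && any(phi > 0)) {
      idx <- which(pos & phi > 0)
      beta <- log(mg[idx])
      ysub <- y[idx, J, drop = FALSE]
      ph <- phi[idx]
      conv <- rep(FALSE, length(idx))
      for (it in seq_len(max_iter)) {
        mu <- exp(beta) %o% sg
        denom <- 1 + ph * mu
        score <- rowSums((ysub - mu) / denom)
        info <- rowSums(mu / denom)
        step <- score / pmax(info, 1e-12)
        step <- pmax(pmin(step, 5), -5)
        beta <- beta + step
        conv <- abs(step) < tol
        if (all(conv)) break
      }
      converged[idx] <- converged[idx] & conv
      mg[idx] <- exp(beta)
    }
    m[, g] <- mg
  }
  mu <- matrix(0, nf, ncol(y))
  for (g in seq_along(groups)) mu[, groups[[g]]] <- m[, g] %o% s[groups[[g]]]
  list(mu = mu, m = m, converged = converged)
}

nb_loglik_rows <- function(y, mu, phi) {
  phi <- rep_len(phi, nrow(y))
  ll <- numeric(nrow(y))
  pois <- phi < 1e-8
  if (any(pois))
    ll[pois] <- rowSums(stats::dpois(y[pois, , drop = FALSE],
                                     pmax(mu[pois, , drop = FALSE], 1e-300),
                                     log = TRUE))
  if (any(!pois)) {
    i <- which(!pois)
    ll[i] <- rowSums(stats::dnbinom(y[i, , drop = FALSE],
                                    size = 1 / phi[i],
                                    mu = pmax(mu[i, , drop = FALSE], 1e-300),
                                    log = TRUE))
  }
  ll
}

#' Estimate negative-binomial dispersion
#'
#' The common dispersion maximises the Cox-Reid adjusted profile
#' likelihood summed over all features (group means profiled out,
#' adjustment `0.5 * log det(X'WX)`). Per-feature dispersions are
#' method-of-moments estimates shrunk toward the common value with a
#' fixed prior weight expressed in degrees of freedom, then clamped to
#' `[1e-6, 10]`.
#'
#' @param cm A [count_matrix()].
#' @param norm A `norm_factors` from [tmm_factors()].
#' @param prior_df Prior weight (in residual degrees of freedom) pulling
#'   per-feature estimates toward the common dispersion (default 10).
#' @return A list of class `dispersion_fit` with `common` (scalar) and
#'   `tagwise` (per-feature vector, named).
#' @export
estimate_dispersion <- function(cm, norm, prior_df = 10) {
  y <- cm$counts
  groups <- split(seq_len(ncol(y)), cm$groups)
  n_rep <- lengths(groups)
  if (!any(n_rep >= 2))
    stop("dispersion is unidentifiable: no group has >= 2 samples")
  s <- norm$effective_lib_sizes / mean(norm$effective_lib_sizes)
  resid_df <- ncol(y) - length(groups)
  apl <- function(log_phi) {
    phi <- exp(log_phi)
    fit <- fit_group_means(y, s, groups, phi)
    ll <- sum(nb_loglik_rows(y, fit$mu, phi))
    w <- fit$mu / (1 + phi * fit$mu)
    adj <- 0
    for (g in seq_along(groups)) {
      wg <- rowSums(w[, groups[[g]], drop = FALSE])
      adj <- adj + 0.5 * sum(log(pmax(wg, 1e-12)))
    }
    ll - adj
  }
  opt <- optimize(apl, lower = log(1e-6), upper = log(10), maximum = TRUE,
                  tol = 1e-4)
  common <- exp(opt$maximum)
  # method-of-moments per feature at the common-dispersion group fit,
  # with the n/(n-p) residual-df correction on the squared residuals
  fit <- fit_group_means(y, s, groups, common)
  dfc <- ncol(y) / max(resid_df, 1)
  num <- dfc * rowSums((y - fit$mu)^2) - rowSums(fit$mu)
  den <- rowSums(fit$mu^2)
  phi_mom <- ifelse(den > 0, pmax(num / den, 0), common)
  tagwise <- (prior_df * common + resid_df * phi_mom) /
             (prior_df + resid_df)
  tagwise <- pmin(pmax(tagwise, 1e-6), 10)
  names(tagwise) <- rownames(y)
  structure(list(common = common, tagwise = tagwise,
                 prior_df = prior_df), class = "dispersion_fit")
}

#' Negative-binomial GLM likelihood-ratio test
#'
#' Per feature, fits the NB log-linear model with offsets
#' `log(effective library size)` under the null (one mean for both
#' groups) and the alternative (one mean per group); the LRT statistic
#' `2 * delta-loglik` is referred to a chi-square with 1 df. Fold
#' changes come from the fitted group means (with a small prior count
#' so all-zero groups stay finite); logCPM is the average normalised
#' abundance on the log2 counts-per-million scale.
#'
#' @param cm A [count_matrix()].
#' @param norm A `norm_factors`.
#' @param dispersion A `dispersion_fit`, or a numeric dispersion
#'   (scalar or per-feature).
#' @param contrast Character vector `c(treatment, control)`; log2FC is
#'   treatment relative to control.
#' @param prior_count Prior count added per group when computing fold
#'   changes (default 0.125).
#' @return A data.frame of class `de_result`: `feature`, `log2FC`,
#'   `logCPM`, `dispersion`, `p_raw` (NA when the fit did not
#'   converge).
#' @export
nb_lrt <- function(cm, norm, dispersion, contrast,
                   prior_count = 0.125) {
  if (length(contrast) != 2L)
    stop("contrast must be c(treatment, control)")
  if (!all(contrast %in% cm$groups))
    stop("contrast groups not present in design: ",
         paste(setdiff(contrast, cm$groups), collapse = ", "))
  keep <- cm$groups %in% contrast
  y <- cm$counts[, keep, drop = FALSE]
  grp <- cm$groups[keep]
  s_eff <- norm$effective_lib_sizes[keep]
  s <- s_eff / mean(s_eff)
  phi <- if (inherits(dispersion, "dispersion_fit"))
    dispersion$tagwise else rep_len(dispersion, nrow(y))
  phi <- pmin(pmax(phi, 0), 10)
  groups2 <- list(treat = which(grp == contrast[1]),
                  ctrl = which(grp == contrast[2]))
  alt <- fit_group_means(y, s, groups2, phi)
  null <- fit_group_means(y, s, list(all = seq_len(ncol(y))), phi)
  ll1 <- nb_loglik_rows(y, alt$mu, phi)
  ll0 <- nb_loglik_rows(y, null$mu, phi)
  stat <- pmax(2 * (ll1 - ll0), 0)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  bad <- !(alt$converged & null$converged)
  p[bad] <- NA_real_
  # prior-augmented group means for finite fold changes
  mt <- (rowSums(y[, groups2$treat, drop = FALSE]) + prior_count) /
        sum(s[groups2$treat])
  mc <- (rowSums(y[, groups2$ctrl, drop = FALSE]) + prior_count) /
        sum(s[groups2$ctrl])
  log2fc <- log2(mt / mc)
  logcpm <- log2((rowSums(y) + 0.5) / (sum(s_eff) + 1) * 1e6)
  res <- data.frame(feature = rownames(y), log2FC = log2fc,
                    logCPM = logcpm, dispersion = phi, p_raw = p,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("de_result", "data.frame")
  res
}

#' Call differential expression at fixed thresholds
#'
#' Benjamini-Hochberg adjusts the raw p-values over all tested
#' features, then labels each feature `up` (log2FC >= `lfc_cut` and
#' FDR < `fdr_cut`), `down` (log2FC <= -`lfc_cut` and FDR < `fdr_cut`)
#' or `not_DE`. The default thresholds (|log2FC| >= 0.7, FDR < 0.01)
#' are deliberately strict for nascent-transcription data.
#'
#' @param results A `de_result` from [nb_lrt()].
#' @param lfc_cut Absolute log2 fold-change threshold (inclusive).
#' @param fdr_cut FDR threshold (exclusive).
#' @return `results` with columns `fdr` and `status` added.
#' @export
classify_de <- function(results, lfc_cut = 0.7, fdr_cut = 0.01) {
  if (nrow(results) == 0L) {
    results$fdr <- numeric(0); results$status <- character(0)
    return(results)
  }
  results$fdr <- p.adjust(results$p_raw, method = "BH")
  de <- !is.na(results$fdr) & results$fdr < fdr_cut
  results$status <- ifelse(de & results$log2FC >= lfc_cut, "up",
                    ifelse(de & results$log2FC <= -lfc_cut, "down",
                           "not_DE"))
  results
}

#' Run the full differential-expression stage
#'
#' Convenience wrapper: [filter_expressed()], [tmm_factors()],
#' [estimate_dispersion()], [nb_lrt()], [classify_de()].
#'
#' @param cm A [count_matrix()].
#' @param contrast `c(treatment, control)`.
#' @param lfc_cut,fdr_cut Passed to [classify_de()].
#' @param prior_df Passed to [estimate_dispersion()].
#' @return A classified `de_result`.
#' @export
de_pipeline <- function(cm, contrast, lfc_cut = 0.7, fdr_cut = 0.01,
                        prior_df = 10) {
  cm <- filter_expressed(cm)
  norm <- tmm_factors(cm)
  disp <- estimate_dispersion(cm, norm, prior_df = prior_df)
  classify_de(nb_lrt(cm, norm, disp, contrast),
              lfc_cut = lfc_cut, fdr_cut = fdr_cut)
}
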