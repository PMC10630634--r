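# Delta-delta-Ct qPCR quantification, time-course correlation, and
# approach-to-equilibrium metabolic-labeling slope estimation.

#' Relative expression by the delta-delta-Ct method
#'
#' Per sample, `dCT = CT_target - CT_reference`; `ddCT` subtracts the
#' mean dCT of the calibrator group (per target gene), and relative
#' expression is `2^-ddCT` (amplification efficiency fixed at perfect
#' doubling; pass `efficiency` for a corrected base). Downstream
#' statistics should be computed on the dCT values, not on the fold
#' changes.
#'
#' @param ct Data.frame with columns `sample`, `group`, `target`,
#'   `ct_target`, `ct_reference` (and anything else, carried through).
#' @param calibrator_group Group label used as the calibrator.
#' @param efficiency Amplification base (default 2).
#' @return `ct` with columns `dct`, `ddct`, `rel_expr` added.
#' @export
ddct <- function(ct, calibrator_group, efficiency = 2) {
  need <- c("sample", "group", "target", "ct_target", "ct_reference")
  if (!all(need %in% names(ct)))
    stop("ct table needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(ct$ct_target)) || any(!is.finite(ct$ct_reference)))
    stop("missing or non-finite CT value")
  if (!calibrator_group %in% ct$group)
    stop("calibrator group '", calibrator_group, "' not present")
  ct$dct <- ct$ct_target - ct$ct_reference
  cal_mean <- tapply(ct$dct[ct$group == calibrator_group],
                     ct$target[ct$group == calibrator_group], mean)
  if (any(!ct$target %in% names(cal_mean)))
    stop("target(s) absent from calibrator group: ",
         paste(setdiff(ct$target, names(cal_mean)), collapse = ", "))
  ct$ddct <- ct$dct - as.vector(cal_mean[ct$target])
  ct$rel_expr <- efficiency^(-ct$ddct)
  ct
}

#' Welch t tests with Bonferroni correction on dCT values
#'
#' One Welch two-sample t test per requested comparison, on the dCT
#' scale; adjusted p = `min(1, m * p)` where `m` is the stated number
#' of comparisons in the family (must be at least the number actually
#' performed).
#'
#' @param dct Numeric vector of per-sample dCT values.
#' @param groups Group label per sample.
#' @param comparisons List of `c(groupA, groupB)` pairs.
#' @param m Family size for the correction (default:
#'   `length(comparisons)`).
#' @return A data.frame with `group_a`, `group_b`, `t`, `p_raw`,
#'   `p_adj`.
#' @export
ttest_bonferroni <- function(dct, groups, comparisons,
                             m = length(comparisons)) {
  if (m < length(comparisons))
    stop("m (", m, ") is smaller than the number of comparisons (",
         length(comparisons), ")")
  one <- function(cmp) {
    a <- dct[groups == cmp[1]]; b <- dct[groups == cmp[2]]
    if (length(a) < 2L || length(b) < 2L)
      stop("need >= 2 samples per group (", cmp[1], " vs ", cmp[2], ")")
    if (var(a) == 0 && var(b) == 0 && mean(a) == mean(b))
      return(c(t = 0, p = 1))
    tt <- t.test(a, b)
    c(t = unname(tt$statistic), p = tt$p.value)
  }
  res <- t(vapply(comparisons, one, c(t = 0, p = 0)))
  data.frame(group_a = vapply(comparisons, `[`, "", 1),
             group_b = vapply(comparisons, `[`, "", 2),
             t = res[, "t"], p_raw = res[, "p"],
             p_adj = pmin(1, m * res[, "p"]),
             stringsAsFactors = FALSE)
}

#' Pearson correlation of expression with time
#'
#' Pools all replicate observations (time as x) and reports Pearson r
#' with a two-sided p from the t transform.
#'
#' @param times,values Paired numeric vectors (>= 3 observations).
#' @return A list with `n`, `pearson_r`, `p_value`; `pearson_r` is `NA`
#'   when either variable has zero variance.
#' @export
timecourse_correlation <- function(times, values) {
  if (length(times) != length(values)) stop("times/values length mismatch")
  if (length(times) < 3L) stop("need at least 3 observations")
  if (var(times) == 0 || var(values) == 0)
    return(list(n = length(times), pearson_r = NA_real_,
                p_value = NA_real_))
  ct <- cor.test(times, values, method = "pearson")
  list(n = length(times), pearson_r = unname(ct$estimate),
       p_value = ct$p.value)
}

#' Fit a synthesis-rate slope from a labeling time course
#'
#' Ordinary least squares of labeled abundance on labeling time with a
#' free intercept; in the approach-to-equilibrium design the slope is
#' the synthesis-rate proxy.
#'
#' @param series Data.frame with columns `time` (minutes) and
#'   `abundance` (relative units), one row per observation.
#' @return A list of class `slope_fit`: `slope`, `intercept`,
#'   `slope_se`, `r_squared`, `n`.
#' @export
fit_synthesis_rate <- function(series) {
  if (!all(c("time", "abundance") %in% names(series)))
    stop("series needs columns 'time' and 'abundance'")
  if (length(unique(series$time)) < 3L)
    stop("need >= 3 distinct labeling times for a slope fit")
  if (any(series$time <= 0)) stop("labeling times must be > 0")
  fit <- lm(abundance ~ time, data = series)
  sm <- suppressWarnings(summary(fit))  # exact lines are legitimate input
  structure(list(slope = unname(coef(fit)["time"]),
                 intercept = unname(coef(fit)["(Intercept)"]),
                 slope_se = sm$coefficients["time", "Std. Error"],
                 r_squared = sm$r.squared,
                 n = nrow(series)), class = "slope_fit")
}

#' Test for a difference between two labeling slopes
#'
#' Pools both series into one linear model with a condition-by-time
#' interaction; the two-sided t test on the interaction coefficient
#' tests slope equality.
#'
#' @param a,b Data.frames with `time` and `abundance` (each fit-able by
#'   [fit_synthesis_rate()]).
#' @return A list with `slope_a`, `slope_b`, `difference`,
#'   `t`, `df`, `p_value`.
#' @export
compare_slopes <- function(a, b) {
  fa <- fit_synthesis_rate(a); fb <- fit_synthesis_rate(b)
  df <- rbind(data.frame(time = a$time, abundance = a$abundance,
                         condition = "a"),
              data.frame(time = b$time, abundance = b$abundance,
                         condition = "b"))
  if (nrow(df) - 4L <= 0L)
    stop("not enough observations for the interaction test")
  fit <- lm(abundance ~ time * condition, data = df)
  sm <- summary(fit)$coefficients
  row <- grep("^time:condition", rownames(sm))
  est <- sm[row, "Estimate"]; se <- sm[row, "Std. Error"]
  if (se == 0) {
    tval <- if (est == 0) 0 else sign(est) * Inf
    p <- if (est == 0) 1 else 0
  } else {
    tval <- est / se
    p <- 2 * pt(abs(tval), df = nrow(df) - 4, lower.tail = FALSE)
  }
  list(slope_a = fa$slope, slope_b = fb$slope,
       difference = fb$slope - fa$slope, t = tval,
       df = nrow(df) - 4, p_value = p)
}
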