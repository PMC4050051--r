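## Agreement statistics for repeated thickness measurements: paired
## differences with t-based CIs, Bland-Altman limits of agreement (the
## small-sample +/- 2 SD rule), two-way single-measure absolute-agreement
## ICC with F-based CIs, absolute and relative coefficients of
## repeatability, and one-way repeated-measures ANOVA on the session factor.

#' Paired session difference with CI and limits of agreement
#'
#' For paired measurements `a` and `b`, computes `d = a - b`, its mean, the
#' t-based 95% confidence interval of the mean, and the 95% limits of
#' agreement for small groups: mean difference +/- 2 standard deviations
#' (sample SD, n-1 denominator).
#'
#' @param a,b Numeric session vectors of equal length `n >= 2`.
#' @return List `mean_diff`, `ci95` (length 2), `loa` (length 2), `sd_diff`,
#'   `n`.
#' @export
paired_diff <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2) stop("need n >= 2 pairs")
  d <- a - b
  m <- mean(d)
  s <- sd(d)
  tq <- qt(0.975, n - 1)
  list(mean_diff = m,
       ci95 = c(m - tq * s / sqrt(n), m + tq * s / sqrt(n)),
       loa = c(m - 2 * s, m + 2 * s),
       sd_diff = s, n = n)
}

#' Bland-Altman pairs and difference-versus-mean association
#'
#' Returns the per-subject (mean, difference) pairs and the Pearson
#' correlation of difference against mean with its p-value, used to check
#' for an association between measurement variability and magnitude. With
#' zero variance in either series the association is undefined and flagged.
#'
#' @param a,b Numeric session vectors, `n >= 3` for the association test.
#' @return List `mean` (`(a+b)/2`), `diff` (`a-b`), `r`, `p`, and
#'   `association_defined`.
#' @export
bland_altman <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  m <- (a + b) / 2
  d <- a - b
  if (var(m) == 0 || var(d) == 0) {
    return(list(mean = m, diff = d, r = NA_real_, p = NA_real_,
                association_defined = FALSE))
  }
  ct <- stats::cor.test(m, d)
  list(mean = m, diff = d, r = unname(ct$estimate), p = ct$p.value,
       association_defined = TRUE)
}

## two-way mean squares of a complete n x k matrix (rows = subjects,
## columns = sessions)
anova_decomposition <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  list(ms_rows = ss_rows / (n - 1), ms_cols = ss_cols / (k - 1),
       ms_err = ss_err / ((n - 1) * (k - 1)), n = n, k = k)
}

#' Absolute-agreement intraclass correlation
#'
#' Two-way, single-measure, absolute-agreement ICC (ICC(A,1)) from the
#' two-way ANOVA decomposition:
#' `(MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))`, with the
#' F-based 95% confidence interval of the same formulation.
#'
#' @param m Complete numeric matrix, rows = subjects (`n >= 2`), columns =
#'   sessions (`k >= 2`).
#' @return List `icc`, `ci95`, `defined` (`FALSE` when the matrix has zero
#'   total variance).
#' @export
icc_absolute <- function(m) {
  m <- as.matrix(m)
  if (any(!is.finite(m))) stop("missing cells are not allowed")
  if (nrow(m) < 2 || ncol(m) < 2) stop("need n >= 2 subjects and k >= 2 sessions")
  if (var(as.vector(m)) == 0)
    return(list(icc = NA_real_, ci95 = c(NA_real_, NA_real_), defined = FALSE))
  a <- anova_decomposition(m)
  n <- a$n; k <- a$k
  icc <- (a$ms_rows - a$ms_err) /
    (a$ms_rows + (k - 1) * a$ms_err + (k / n) * (a$ms_cols - a$ms_err))
  ## F-based CI (McGraw & Wong formulation for ICC(A,1))
  alpha <- 0.05
  fj <- a$ms_cols / a$ms_err
  aa <- (k * icc) / (n * (1 - icc))
  bb <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (aa * a$ms_cols + bb * a$ms_err)^2 /
    ((aa * a$ms_cols)^2 / (k - 1) + (bb * a$ms_err)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lo <- n * (a$ms_rows - f_l * a$ms_err) /
    (f_l * (k * a$ms_cols + (k * n - k - n) * a$ms_err) + n * a$ms_rows)
  hi <- n * (f_u * a$ms_rows - a$ms_err) /
    (k * a$ms_cols + (k * n - k - n) * a$ms_err + n * f_u * a$ms_rows)
  list(icc = icc, ci95 = c(lo, hi), defined = TRUE)
}

#' Coefficient of repeatability
#'
#' `cr_abs = 1.96 * SD(d)` for the paired differences `d`; the relative
#' coefficient `cr_pct` expresses it as a percentage of the grand mean of
#' all measurements entering the differences.
#'
#' @param d Numeric vector of paired differences, `n >= 2`.
#' @param grand_mean Mean of all measurements entering `d`; must be > 0 for
#'   `cr_pct`.
#' @return List `cr_abs`, `cr_pct` (`NA` when `grand_mean <= 0`).
#' @export
coefficient_of_repeatability <- function(d, grand_mean) {
  if (length(d) < 2) stop("need n >= 2 differences")
  cr_abs <- 1.96 * sd(d)
  cr_pct <- if (is.finite(grand_mean) && grand_mean > 0)
    100 * cr_abs / grand_mean else NA_real_
  list(cr_abs = cr_abs, cr_pct = cr_pct)
}

#' One-way repeated-measures ANOVA on the session factor
#'
#' `F = MS_session / MS_(session x subject)` with degrees of freedom
#' `(k - 1, (k - 1)(n - 1))`.
#'
#' @param m Complete numeric matrix, rows = subjects, columns = sessions.
#' @return List `F`, `p`, `df`.
#' @export
rm_anova <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need n >= 2 subjects and k >= 2 sessions")
  if (any(!is.finite(m))) stop("missing cells are not allowed")
  a <- anova_decomposition(m)
  df1 <- a$k - 1; df2 <- (a$k - 1) * (a$n - 1)
  F <- if (a$ms_err > 0) a$ms_cols / a$ms_err else
    if (a$ms_cols == 0) 0 else Inf
  p <- pf(F, df1, df2, lower.tail = FALSE)
  list(F = F, p = p, df = c(df1, df2))
}

#' Agreement-statistics report across layers, fields and session pairs
#'
#' Builds the repeatability table: one row per layer x field x session
#' comparison (each later session against the first), carrying the mean
#' difference with CI and limits of agreement, the absolute-agreement ICC
#' with CI over all sessions, absolute and relative coefficients of
#' repeatability, and the repeated-measures ANOVA p over all sessions.
#'
#' @param measurements Long-format data frame with columns `subject`,
#'   `session`, `layer`, `field`, `value`; every subject must appear in
#'   every session within a layer/field.
#' @return A `repeatability_report` data frame.
#' @export
build_report <- function(measurements) {
  need <- c("subject", "session", "layer", "field", "value")
  if (!all(need %in% names(measurements)))
    stop(sprintf("measurements must have columns: %s",
                 paste(need, collapse = ", ")))
  out <- list()
  for (layer in unique(measurements$layer))
    for (field in unique(measurements$field)) {
      sub <- measurements[measurements$layer == layer &
                          measurements$field == field, ]
      if (!nrow(sub)) next
      sessions <- sort(unique(sub$session))
      if (length(sessions) < 2) stop("need at least two sessions per layer/field")
      subjects <- sort(unique(sub$subject))
      m <- matrix(NA_real_, length(subjects), length(sessions),
                  dimnames = list(subjects, sessions))
      for (i in seq_len(nrow(sub)))
        m[as.character(sub$subject[i]), as.character(sub$session[i])] <-
          sub$value[i]
      if (any(!is.finite(m)))
        stop(sprintf("inconsistent subject sets across sessions (%s, %s)",
                     layer, field))
      icc <- icc_absolute(m)
      aov_p <- rm_anova(m)$p
      for (s in seq_along(sessions)[-1]) {
        a <- m[, 1]; b <- m[, s]
        pd <- paired_diff(b, a)
        cr <- coefficient_of_repeatability(b - a, mean(c(a, b)))
        out[[length(out) + 1L]] <- data.frame(
          layer = layer, field = field,
          comparison = sprintf("%s-%s", sessions[1], sessions[s]),
          n = pd$n, mean_diff = pd$mean_diff,
          ci_low = pd$ci95[1], ci_high = pd$ci95[2],
          loa_low = pd$loa[1], loa_high = pd$loa[2],
          icc = icc$icc, icc_ci_low = icc$ci95[1], icc_ci_high = icc$ci95[2],
          cr_abs = cr$cr_abs, cr_pct = cr$cr_pct, anova_p = aov_p)
      }
    }
  out <- do.call(rbind, out)
  class(out) <- c("repeatability_report", "data.frame")
  out
}

#' @export
print.repeatability_report <- function(x, ...) {
  cat("Repeatability report:\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf(
      "  %-8s %-6s %-6s d=%6.1f (CI %6.1f..%6.1f, LoA %6.1f..%6.1f)  ICC %.3f (%.3f..%.3f)  CR %.1f (%.0f%%)  p=%.3g\n",
      x$layer[i], x$field[i], x$comparison[i], x$mean_diff[i],
      x$ci_low[i], x$ci_high[i], x$loa_low[i], x$loa_high[i],
      x$icc[i], x$icc_ci_low[i], x$icc_ci_high[i],
      x$cr_abs[i], x$cr_pct[i], x$anova_p[i]))
  invisible(x)
}
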