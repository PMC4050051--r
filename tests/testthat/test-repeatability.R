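# Brute-force oracles: plain sums-of-squares and textbook formulas, kept
# separate from the implementation's code paths.
ss_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m); g <- mean(m)
  list(ms_rows = k * sum((rowMeans(m) - g)^2) / (n - 1),
       ms_cols = n * sum((colMeans(m) - g)^2) / (k - 1),
       ms_err = (sum((m - g)^2) - k * sum((rowMeans(m) - g)^2) -
                   n * sum((colMeans(m) - g)^2)) / ((n - 1) * (k - 1)))
}

test_that("paired differences give the +/-2 SD limits of agreement exactly", {
  pd0 <- paired_diff(c(1, 2, 3), c(1, 2, 3))
  expect_equal(pd0$mean_diff, 0)
  expect_equal(pd0$loa, c(0, 0))

  pd <- paired_diff(c(2, 4, 6), c(1, 2, 3))  # d = 1, 2, 3
  expect_equal(pd$mean_diff, 2)
  expect_equal(pd$sd_diff, 1)
  expect_equal(pd$loa, c(0, 4))  # mean +/- 2 SD
  ## t-based CI with the frozen quantile t_{0.975, 2} = 4.302653
  expect_equal(pd$ci95, 2 + c(-1, 1) * 4.302653 / sqrt(3), tolerance = 1e-6)
  expect_error(paired_diff(1, 2), "n >= 2")

  ## LoA width is exactly 4 SD for arbitrary data
  set.seed(1)
  a <- rnorm(12, 100, 10); b <- rnorm(12, 100, 10)
  pd2 <- paired_diff(a, b)
  expect_equal(diff(pd2$loa), 4 * sd(a - b))
})

test_that("Bland-Altman flags degenerate series and matches the correlation oracle", {
  a <- c(1, 2, 3, 4)
  ba0 <- bland_altman(a + 5, a)  # constant offset: zero-variance differences
  expect_false(ba0$association_defined)

  set.seed(2)
  x <- runif(20, 50, 150)
  ba1 <- bland_altman(0.5 * x, x)  # proportional bias
  expect_lt(ba1$r, -0.99)          # |diff| grows with the mean

  set.seed(3)
  u <- rnorm(10, 100, 15); v <- u + rnorm(10, 0, 5)
  ba <- bland_altman(u, v)
  mm <- (u + v) / 2; dd <- u - v
  r_manual <- sum((mm - mean(mm)) * (dd - mean(dd))) /
    sqrt(sum((mm - mean(mm))^2) * sum((dd - mean(dd))^2))
  expect_equal(ba$r, r_manual, tolerance = 1e-12)
})

test_that("the absolute-agreement ICC matches its ANOVA definition", {
  ## identical sessions: perfect agreement
  v <- c(3, 1, 4, 1, 5)
  expect_equal(icc_absolute(cbind(v, v))$icc, 1)

  ## 5 x 2 fixture against brute-force sums of squares
  m <- matrix(c(9, 6, 8, 7, 10, 9.5, 6.2, 8.4, 6.9, 10.3), 5, 2)
  ss <- ss_oracle(m)
  k <- 2; n <- 5
  icc_o <- (ss$ms_rows - ss$ms_err) /
    (ss$ms_rows + (k - 1) * ss$ms_err + (k / n) * (ss$ms_cols - ss$ms_err))
  out <- icc_absolute(m)
  expect_equal(out$icc, icc_o, tolerance = 1e-9)
  expect_true(out$ci95[1] <= out$icc && out$icc <= out$ci95[2])

  ## invariance under common affine rescaling
  out2 <- icc_absolute(3.2 * m + 40)
  expect_equal(out2$icc, out$icc, tolerance = 1e-12)

  ## independent columns: ICC concentrates near zero
  set.seed(4)
  null_m <- matrix(rnorm(1500), 500, 3)
  expect_lt(abs(icc_absolute(null_m)$icc), 0.1)

  expect_true(!icc_absolute(matrix(5, 4, 2))$defined)
  expect_error(icc_absolute(matrix(c(1, NA, 3, 4), 2, 2)), "missing")
})

test_that("the coefficient of repeatability is 1.96 SD of the differences", {
  d <- c(-1, 0, 1)  # SD 1
  cr <- coefficient_of_repeatability(d, 100)
  expect_equal(cr$cr_abs, 1.96)
  expect_equal(cr$cr_pct, 1.96)
  cr0 <- coefficient_of_repeatability(c(0, 0, 0), 50)
  expect_equal(cr0$cr_abs, 0)
  expect_equal(cr0$cr_pct, 0)
  expect_true(is.na(coefficient_of_repeatability(d, 0)$cr_pct))

  set.seed(5)
  dd <- rnorm(15, 0, 7); gm <- 123.4
  cr2 <- coefficient_of_repeatability(dd, gm)
  expect_equal(cr2$cr_abs, 1.96 * sd(dd), tolerance = 1e-12)
  expect_equal(cr2$cr_pct, 100 * 1.96 * sd(dd) / gm, tolerance = 1e-12)
})

test_that("repeated-measures ANOVA agrees with aov() and its degenerate limits", {
  v <- c(3, 1, 4, 1, 5)
  r0 <- rm_anova(cbind(v, v, v))
  expect_equal(r0$F, 0)
  expect_equal(r0$p, 1)

  set.seed(6)
  base <- rnorm(8, 100, 10)
  shifted <- cbind(base, base + 100 * 10, base + rnorm(8, 0, 1))
  expect_lt(rm_anova(shifted)$p, 0.001)

  ## 6 x 3 fixture against the aov() decomposition
  m <- matrix(rnorm(18, 100, 12), 6, 3)
  r <- rm_anova(m)
  long <- data.frame(y = as.vector(m),
                     subj = factor(rep(seq_len(6), 3)),
                     sess = factor(rep(seq_len(3), each = 6)))
  fit <- summary(stats::aov(y ~ sess + Error(subj / sess), data = long))
  tab <- fit[["Error: subj:sess"]][[1]]
  expect_equal(r$F, tab["sess", "F value"], tolerance = 1e-9)
  expect_equal(r$p, tab["sess", "Pr(>F)"], tolerance = 1e-9)
  expect_equal(r$df, c(2, 10))
})

test_that("the report composes the standalone statistics per layer and field", {
  set.seed(7)
  subj <- sprintf("s%02d", 1:10)
  vals <- matrix(rnorm(30, 150, 30), 10, 3)
  long <- do.call(rbind, lapply(1:3, function(s)
    data.frame(subject = subj, session = paste0("R", s),
               layer = "haller", field = "csm", value = vals[, s])))
  long2 <- long
  long2$layer <- "sattler"
  long2$value <- long2$value / 2
  rep <- build_report(rbind(long, long2))
  expect_equal(nrow(rep), 2L * 1L * 2L)  # layers x fields x comparisons

  row <- rep[rep$layer == "haller" & rep$comparison == "R1-R2", ]
  pd <- paired_diff(vals[, 2], vals[, 1])
  expect_equal(row$mean_diff, pd$mean_diff)
  expect_equal(c(row$loa_low, row$loa_high), pd$loa)
  expect_equal(row$icc, icc_absolute(vals)$icc)
  cr <- coefficient_of_repeatability(vals[, 2] - vals[, 1],
                                     mean(vals[, 1:2]))
  expect_equal(row$cr_abs, cr$cr_abs)
  expect_equal(row$anova_p, rm_anova(vals)$p)

  ## identical sessions: exact perfect-agreement row
  same <- rbind(
    data.frame(subject = subj, session = "R1", layer = "h", field = "csm",
               value = vals[, 1]),
    data.frame(subject = subj, session = "R2", layer = "h", field = "csm",
               value = vals[, 1]))
  rep0 <- build_report(same)
  expect_equal(rep0$mean_diff, 0)
  expect_equal(rep0$icc, 1)
  expect_equal(rep0$cr_abs, 0)

  ## inconsistent subject sets are rejected
  bad <- rbind(long, long2)
  bad <- bad[-1, ]
  expect_error(build_report(bad), "inconsistent")
})
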