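test_that("success rates match exact proportions", {
  sr <- success_rate(c(rep(TRUE, 816), rep(FALSE, 24)))
  expect_equal(sr$percent, 97.14)
  expect_equal(success_rate(c(rep(TRUE, 738), rep(FALSE, 102)))$percent, 87.86)
  expect_equal(success_rate(c(rep(TRUE, 817), rep(FALSE, 23)))$percent, 97.26)
  expect_equal(success_rate(rep(FALSE, 10))$percent, 0)
  # success + failure complement exactly at stored precision
  expect_identical(sr$rate + sr$failures / sr$n, 1)
  expect_error(success_rate(logical(0)), "empty")
})

test_that("Cohen's kappa matches hand-computed tables", {
  expect_equal(cohens_kappa(agreement_table(244, 0, 1, 35))$kappa, 0.984,
               tolerance = 5e-4)
  expect_equal(cohens_kappa(agreement_table(271, 0, 0, 9))$kappa, 1)
  expect_equal(cohens_kappa(agreement_table(270, 0, 2, 8))$kappa, 0.885,
               tolerance = 5e-4)
  expect_equal(cohens_kappa(agreement_table(10, 0, 0, 10))$kappa, 1)
  # hand oracle: p_o = 0.60, p_e = 0.54
  k <- cohens_kappa(agreement_table(45, 15, 25, 15))
  expect_equal(k$p_o, 0.6)
  expect_equal(k$p_e, 0.54)
  expect_equal(k$kappa, 0.06 / 0.46, tolerance = 1e-10)
  expect_equal(round(k$kappa, 4), 0.1304)
  # degenerate all-one-cell table
  expect_equal(cohens_kappa(agreement_table(20, 0, 0, 0))$kappa, 1)
  expect_error(agreement_table(-1, 0, 0, 5), "nonnegative")
  # symmetry in raters: transposing the table (swap b and c) is invariant
  expect_equal(cohens_kappa(agreement_table(45, 25, 15, 15))$kappa,
               k$kappa, tolerance = 1e-12)
})

test_that("ICC(2,1) matches the explicit sums-of-squares oracle", {
  set.seed(10)
  x <- rnorm(10, 10, 2)
  expect_equal(icc_2_1(cbind(x, x))$icc, 1)

  block <- rbind(c(9, 2), c(1, 10), c(8, 6), c(2, 4), c(7, 6), c(10, 2))
  # oracle: explicit two-way ANOVA decomposition
  n <- 6; k <- 2
  grand <- mean(block)
  msr <- k * sum((rowMeans(block) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(block) - grand)^2) / (k - 1)
  mse <- (sum((block - grand)^2) - (n - 1) * msr - (k - 1) * msc) /
    ((n - 1) * (k - 1))
  icc_oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  res <- icc_2_1(block)
  expect_equal(res$icc, icc_oracle, tolerance = 1e-10)
  expect_equal(res$msr, msr, tolerance = 1e-10)
  expect_lt(res$ci[1], res$icc)
  expect_gt(res$ci[2], res$icc)

  # closed-form expectation: equal subject and error variance -> ICC 1/2
  set.seed(11)
  s <- rnorm(2000)
  blk <- cbind(s + rnorm(2000), s + rnorm(2000))
  expect_equal(icc_2_1(blk)$icc, 0.5, tolerance = 0.06)

  expect_error(icc_2_1(matrix(5, 4, 2)), "zero variance")
  expect_message(icc_2_1(rbind(c(1, 2), c(2, NA), c(3, 5), c(4, 4))),
                 "dropped")
})

test_that("ICC is invariant to affine rescaling of all ratings", {
  set.seed(12)
  blk <- matrix(rnorm(30, 8, 2), 10, 3)
  a <- icc_2_1(blk)$icc
  expect_equal(icc_2_1(blk * 3.7 + 11)$icc, a, tolerance = 1e-12)
})

test_that("Friedman test equals the literal rank oracle", {
  blk <- rbind(c(3, 1, 2), c(9, 7, 8), c(2, 1, 3), c(6, 4, 5))
  res <- friedman_test(blk)
  # oracle: literal within-row ranks, classic statistic (no ties here)
  Rj <- colSums(t(apply(blk, 1, rank)))
  n <- 4; k <- 3
  stat <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  expect_equal(res$statistic, stat, tolerance = 1e-10)
  expect_equal(res$df, 2L)

  # identical values everywhere: no evidence
  res0 <- friedman_test(matrix(5, 4, 3))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  # two conditions reduce to a sign-test-equivalent statistic
  set.seed(3)
  b2 <- cbind(rnorm(12), rnorm(12))
  r2 <- friedman_test(b2)
  s <- sum(b2[, 1] > b2[, 2])
  expect_equal(r2$statistic, (2 * s - 12)^2 / 12, tolerance = 1e-10)

  expect_message(friedman_test(rbind(c(1, 2, 3), c(2, NA, 1),
                                     c(3, 1, 2), c(1, 3, 2))), "dropped")
  expect_error(friedman_test(matrix(1, 3, 1)), "2 conditions")
  # invariance under a strictly monotone transform of each row
  blk2 <- t(apply(blk, 1, function(r) exp(r / 2)))
  expect_equal(friedman_test(blk2)$statistic, res$statistic)
})

test_that("Cochran's Q equals its formula oracle and McNemar at k = 2", {
  bb <- rbind(c(1, 1, 0), c(1, 0, 0), c(1, 1, 1), c(0, 1, 0), c(1, 1, 0),
              c(1, 0, 1))
  q <- cochran_q(bb)
  k <- 3; Cj <- colSums(bb); Ri <- rowSums(bb)
  expect_equal(q$statistic,
               k * (k - 1) * sum((Cj - mean(Cj))^2) /
                 (k * sum(Ri) - sum(Ri^2)), tolerance = 1e-12)
  expect_equal(q$df, 2L)
  # k = 2: Q equals the uncorrected McNemar statistic (b - c)^2 / (b + c)
  set.seed(5)
  b2 <- matrix(rbinom(40, 1, 0.5), 20, 2)
  q2 <- cochran_q(b2)
  b_ <- sum(b2[, 1] == 1 & b2[, 2] == 0)
  c_ <- sum(b2[, 1] == 0 & b2[, 2] == 1)
  expect_equal(q2$statistic, (b_ - c_)^2 / (b_ + c_), tolerance = 1e-12)
  # degenerate: all subjects constant
  expect_error(cochran_q(matrix(1, 5, 3)), "undefined")
  expect_error(cochran_q(matrix(2, 5, 3)), "binary")
})

test_that("grouped error summaries give exact t intervals", {
  rec <- tibble::tibble(position = rep(c(1, 2, 6, 7), each = 3),
                        measured = rep(c(8.2, 8.2, 10.2, 10.2), each = 3),
                        reference = rep(c(8.0, 8.0, 10.0, 10.0), each = 3))
  rec$measured <- rec$measured + rep(c(-0.1, 0, 0.1), 4)
  out <- summarize_errors(rec)
  expect_equal(nrow(out), 2L)          # incisal and molar groups
  expect_equal(out$mean_error, c(0.2, 0.2), tolerance = 1e-12)
  # closed-form t interval
  hw <- stats::qt(0.975, 5) * stats::sd(c(-0.1, 0, 0.1, -0.1, 0, 0.1)) / sqrt(6)
  expect_equal(out$ci_hi - out$mean_error, rep(hw, 2), tolerance = 1e-12)
  # measured == reference everywhere: mean 0, CI spans 0
  rec0 <- rec; rec0$measured <- rec0$reference + rep(c(-0.01, 0, 0.01), 4)
  out0 <- summarize_errors(rec0)
  expect_true(all(out0$ci_lo < 0 & out0$ci_hi > 0))
  # a fully failed group is omitted with a warning
  rec$success <- rep(c(TRUE, FALSE), c(6, 6))
  expect_warning(out2 <- summarize_errors(rec), "omitted")
  expect_equal(as.character(out2$group), "incisal")
})

test_that("tidy/glance methods return one-row tibbles", {
  k <- cohens_kappa(agreement_table(45, 15, 25, 15))
  expect_s3_class(tidy(k), "tbl_df")
  expect_equal(nrow(tidy(k)), 1L)
  set.seed(2)
  expect_named(tidy(icc_2_1(matrix(rnorm(20, 5), 10, 2))),
               c("estimate", "conf.low", "conf.high", "p.value", "n", "k"))
  expect_equal(nrow(tidy(friedman_test(rbind(c(1, 2), c(2, 3), c(1, 3))))), 1L)
  expect_equal(nrow(tidy(cochran_q(rbind(c(1, 0), c(0, 1), c(1, 1),
                                         c(1, 0))))), 1L)
})
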