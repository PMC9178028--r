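#' Segmentation success rate
#'
#' @param outcomes logical (or 0/1) vector of per-tooth success flags.
#' @return tibble with `n`, `successes`, `failures`, `rate` (exact
#'   proportion) and `percent` (rounded to 2 decimals, the reporting
#'   convention).
#' @export
success_rate <- function(outcomes) {
  if (length(outcomes) == 0L) stop("empty outcome vector", call. = FALSE)
  x <- as.logical(outcomes)
  if (anyNA(x)) stop("outcomes must be TRUE/FALSE", call. = FALSE)
  tibble::tibble(n = length(x), successes = sum(x), failures = sum(!x),
                 rate = mean(x), percent = round(100 * mean(x), 2))
}

#' 2 x 2 agreement table
#'
#' Success/failure counts of two rating sessions: `a` = both success,
#' `b` = first success / second failure, `c` = first failure / second
#' success, `d` = both failure.
#'
#' @param a,b,c,d nonnegative integer counts.
#' @return an `agreement_table`.
#' @export
agreement_table <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (sum(counts) < 1) stop("table must contain at least one rating", call. = FALSE)
  structure(as.list(counts), class = "agreement_table")
}

#' Cohen's kappa for a 2 x 2 agreement table
#'
#' kappa = (p_o - p_e) / (1 - p_e) with observed agreement
#' p_o = (a + d) / n and chance agreement p_e from the marginal products.
#' A degenerate all-one-cell table (p_o = p_e = 1) returns kappa = 1.
#'
#' @param t an [agreement_table()] (or four counts via `...`).
#' @return object of class `kappa_result`: list with `kappa`, `p_o`,
#'   `p_e`, `n`, `se` (large-sample), `p_value` (H0: kappa = 0).
#' @export
cohens_kappa <- function(t) {
  stopifnot(inherits(t, "agreement_table"))
  n <- t$a + t$b + t$c + t$d
  p_o <- (t$a + t$d) / n
  p_e <- ((t$a + t$b) * (t$a + t$c) + (t$c + t$d) * (t$b + t$d)) / n^2
  kap <- if (p_e == 1) {
    if (p_o == 1) 1 else NaN
  } else (p_o - p_e) / (1 - p_e)
  se <- if (p_e < 1) sqrt(p_o * (1 - p_o) / n) / (1 - p_e) else NA_real_
  # null (kappa = 0) standard error, Fleiss et al.; marginal proportions
  r1 <- (t$a + t$b) / n; c1 <- (t$a + t$c) / n
  r2 <- 1 - r1; c2 <- 1 - c1
  se0 <- sqrt(p_e + p_e^2 - (r1 * c1 * (r1 + c1) + r2 * c2 * (r2 + c2))) /
    ((1 - p_e) * sqrt(n))
  p_val <- if (is.finite(se0) && se0 > 0)
    2 * stats::pnorm(-abs(kap) / se0) else NA_real_
  structure(list(kappa = kap, p_o = p_o, p_e = p_e, n = n, se = se,
                 p_value = p_val), class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f  (p_o = %.4f, p_e = %.4f, n = %d)\n",
              x$kappa, x$p_o, x$p_e, x$n))
  invisible(x)
}

#' Intraclass correlation ICC(2,1) with 95% confidence interval
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC from the
#' two-way ANOVA mean squares:
#' ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n).
#' The confidence interval is the standard F-based interval.
#'
#' @param block numeric matrix or data frame, subjects x raters/conditions;
#'   rows containing missing values are dropped (complete-case) with a
#'   message.
#' @param conf confidence level.
#' @return object of class `icc_result`: `icc`, `ci` (length 2), mean
#'   squares, `n`, `k`, `p_value` (H0: ICC = 0).
#' @export
icc_2_1 <- function(block, conf = 0.95) {
  block <- as.matrix(block)
  if (ncol(block) < 2L || nrow(block) < 2L)
    stop("need at least 2 subjects and 2 raters", call. = FALSE)
  cc <- stats::complete.cases(block)
  if (!all(cc)) {
    message(sum(!cc), " incomplete row(s) dropped")
    block <- block[cc, , drop = FALSE]
  }
  n <- nrow(block); k <- ncol(block)
  if (n < 2L) stop("fewer than 2 complete rows", call. = FALSE)
  grand <- mean(block)
  row_m <- rowMeans(block); col_m <- colMeans(block)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((block - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (msr == 0 && mse == 0)
    stop("zero variance everywhere: ICC undefined", call. = FALSE)
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  # F-based CI (Shrout & Fleiss / McGraw & Wong)
  alpha <- 1 - conf
  fj <- msc / mse
  vn <- (k - 1) * (n - 1) * ((k * icc * fj + n * (1 + (k - 1) * icc) -
                                k * icc))^2
  vd <- (n - 1) * k^2 * icc^2 * fj^2 +
    (n * (1 + (k - 1) * icc) - k * icc)^2
  v <- vn / vd
  f_obs <- msr / mse
  fl <- f_obs / stats::qf(1 - alpha / 2, n - 1, v)
  fu <- f_obs * stats::qf(1 - alpha / 2, v, n - 1)
  lower <- (fl - 1) / (fl + (k - 1))
  upper <- (fu - 1) / (fu + (k - 1))
  p_value <- stats::pf(f_obs, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  structure(list(icc = icc, ci = c(lower, upper), msr = msr, msc = msc,
                 mse = mse, n = n, k = k, conf = conf, p_value = p_value),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.3f  %.0f%% CI [%.3f, %.3f]  (n = %d, k = %d)\n",
              x$icc, 100 * x$conf, x$ci[1], x$ci[2], x$n, x$k))
  invisible(x)
}

#' Friedman rank test across conditions
#'
#' Within-subject ranks with mid-rank ties, chi-square statistic on k - 1
#' degrees of freedom. Rows with missing values are dropped (complete-case,
#' mirroring measurements lost to segmentation failure).
#'
#' @param block numeric matrix, subjects x conditions (k >= 2).
#' @return `friedman_result`: `statistic`, `df`, `p_value`, `n_used`.
#' @export
friedman_test <- function(block) {
  block <- as.matrix(block)
  if (ncol(block) < 2L) stop("need at least 2 conditions", call. = FALSE)
  cc <- stats::complete.cases(block)
  if (!all(cc)) message(sum(!cc), " incomplete row(s) dropped")
  block <- block[cc, , drop = FALSE]
  if (nrow(block) < 2L) stop("fewer than 2 usable rows", call. = FALSE)
  ht <- stats::friedman.test(block)
  stat <- unname(ht$statistic); p <- ht$p.value
  if (!is.finite(stat)) {   # every row completely tied: no evidence at all
    stat <- 0; p <- 1
  }
  structure(list(statistic = stat, df = unname(ht$parameter),
                 p_value = p, n_used = nrow(block)),
            class = "friedman_result")
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf("Friedman chi-squared = %.4f, df = %d, p = %.4g (n = %d)\n",
              x$statistic, x$df, x$p_value, x$n_used))
  invisible(x)
}

#' Cochran's Q test for related binary outcomes
#'
#' Q = k (k - 1) sum_j (C_j - Cbar)^2 / (k sum_i R_i - sum_i R_i^2) with
#' column totals C_j and row totals R_i; p-value from the chi-square
#' distribution with k - 1 degrees of freedom. Rows with constant outcomes
#' contribute through the formula and are not dropped.
#'
#' @param block binary matrix, subjects x conditions (k >= 2).
#' @return `cochran_q_result`: `statistic`, `df`, `p_value`, `n`.
#' @export
cochran_q <- function(block) {
  block <- as.matrix(block)
  if (ncol(block) < 2L) stop("need at least 2 conditions", call. = FALSE)
  if (!all(block %in% c(0, 1)))
    stop("entries must be binary (0/1 or logical)", call. = FALSE)
  k <- ncol(block)
  Cj <- colSums(block); Ri <- rowSums(block)
  denom <- k * sum(Ri) - sum(Ri^2)
  if (denom == 0)
    stop("all subjects constant across conditions: Q undefined", call. = FALSE)
  Q <- k * (k - 1) * sum((Cj - mean(Cj))^2) / denom
  structure(list(statistic = Q, df = k - 1L,
                 p_value = stats::pchisq(Q, k - 1, lower.tail = FALSE),
                 n = nrow(block)), class = "cochran_q_result")
}

#' @export
print.cochran_q_result <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.4f, df = %d, p = %.4g (n = %d)\n",
              x$statistic, x$df, x$p_value, x$n))
  invisible(x)
}

#' Grouped measurement-error summary
#'
#' Mean (measured - reference) with t-based 95% CI per tooth group, the
#' shape used to compare crown measurements across segmentation methods.
#' Records from failed segmentations enter as missing and are excluded
#' (complete-case within group).
#'
#' @param records tibble with columns `group` (or `position`), `measured`,
#'   `reference`, and optionally `success`.
#' @param conf confidence level.
#' @return tibble: `group`, `n`, `mean_error`, `ci_lo`, `ci_hi`. Groups
#'   with fewer than 2 usable pairs are omitted with a warning.
#' @export
summarize_errors <- function(records, conf = 0.95) {
  stopifnot(all(c("measured", "reference") %in% names(records)))
  if (!"group" %in% names(records)) {
    stopifnot("position" %in% names(records))
    records$group <- tooth_group_of_position(records$position)
  }
  if ("success" %in% names(records))
    records$measured[!records$success %in% TRUE] <- NA_real_
  out <- records |>
    dplyr::mutate(error = .data$measured - .data$reference) |>
    dplyr::filter(is.finite(.data$error)) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_error = mean(.data$error),
                     sd = stats::sd(.data$error), .groups = "drop")
  present <- unique(records$group)
  kept <- out$group[out$n >= 2L]
  dropped <- setdiff(as.character(present), as.character(kept))
  if (length(dropped))
    warning("group(s) omitted (fewer than 2 usable pairs): ",
            paste(dropped, collapse = ", "))
  out <- out[out$n >= 2L, , drop = FALSE]
  tq <- stats::qt(1 - (1 - conf) / 2, out$n - 1)
  hw <- tq * out$sd / sqrt(out$n)
  tibble::tibble(group = out$group, n = out$n, mean_error = out$mean_error,
                 ci_lo = out$mean_error - hw, ci_hi = out$mean_error + hw)
}

## ------------------------------------------------------- broom methods

#' Tidy methods for the agreement statistics
#'
#' @param x a `kappa_result`, `icc_result`, `friedman_result` or
#'   `cochran_q_result`.
#' @param ... unused.
#' @return a one-row tibble of estimates (`tidy`) or fit summaries
#'   (`glance`).
#' @export
tidy.kappa_result <- function(x, ...) {
  tibble::tibble(estimate = x$kappa, p.value = x$p_value,
                 observed_agreement = x$p_o, chance_agreement = x$p_e,
                 n = x$n)
}

#' @rdname tidy.kappa_result
#' @export
tidy.icc_result <- function(x, ...) {
  tibble::tibble(estimate = x$icc, conf.low = x$ci[1], conf.high = x$ci[2],
                 p.value = x$p_value, n = x$n, k = x$k)
}

#' @rdname tidy.kappa_result
#' @export
tidy.friedman_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p_value,
                 n = x$n_used)
}

#' @rdname tidy.kappa_result
#' @export
tidy.cochran_q_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p_value,
                 n = x$n)
}

#' @rdname tidy.kappa_result
#' @export
glance.dgcnn_model <- function(x, ...) {
  fin <- utils::tail(x$log, 1)
  tibble::tibble(n_classes = x$params$n_classes, preset = x$params$preset,
                 epochs = nrow(x$log), final_loss = fin$loss,
                 final_accuracy = fin$accuracy)
}

#' Generic tidiers
#' @param x object to tidy.
#' @param ... passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")
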