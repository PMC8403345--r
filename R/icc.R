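# Agreement statistics for reader/modality reliability studies: two-way
# ANOVA intraclass correlation (absolute agreement, single measures) with
# F-based confidence intervals, standard error of measurement, and the paired
# comparison of modalities.

#' Intraclass correlation, absolute agreement, single measures
#'
#' Computes ICC(A,1) from a complete units-by-raters matrix via the two-way
#' ANOVA decomposition:
#' \deqn{ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with rows (units) mean square \eqn{MS_R}, columns (raters) mean square
#' \eqn{MS_C} and error mean square \eqn{MS_E}. The 95% confidence interval
#' uses the F-based procedure with Satterthwaite degrees of freedom. The
#' `model` tag records whether the design is interpreted as two-way random
#' (both factors sampled; inter-reader use) or two-way mixed (raters fixed;
#' inter-modality use); the absolute-agreement single-measures point estimate
#' and interval are identical under both, so the tag only affects reporting.
#'
#' @param data An n x k numeric matrix (or data frame), n units (>= 2) by k
#'   raters (>= 2), without missing entries (apply listwise deletion first).
#' @param model `"random"` or `"mixed"`.
#' @param conf_level Confidence level of the interval.
#' @return An object of class `fem_icc`: `estimate`, `conf_low`, `conf_high`,
#'   `model`, `n`, `k`, `ms` (named vector of `MSR`, `MSC`, `MSE`),
#'   `conf_level`.
#' @export
#' @examples
#' m <- cbind(a = c(1, 2, 3, 4, 5, 6), b = c(1.1, 2.2, 2.9, 4.2, 4.8, 6.1))
#' icc_agreement_single(m)
icc_agreement_single <- function(data, model = c("random", "mixed"),
                                 conf_level = 0.95) {
  model <- match.arg(model)
  M <- as.matrix(data)
  storage.mode(M) <- "double"
  if (anyNA(M)) {
    abort("ICC input must be complete; apply listwise deletion first",
          class = "femtor_error_missing")
  }
  n <- nrow(M)
  k <- ncol(M)
  if (n < 2L || k < 2L) {
    abort("ICC needs at least 2 units and 2 raters",
          class = "femtor_error_insufficient")
  }
  mu <- mean(M)
  rm_ <- rowMeans(M)
  cm <- colMeans(M)
  MSR <- k * sum((rm_ - mu)^2) / (n - 1)
  MSC <- n * sum((cm - mu)^2) / (k - 1)
  MSE <- sum((M - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + mu)^2) /
    ((n - 1) * (k - 1))
  if (MSR < 1e-300 && MSC < 1e-300 && MSE < 1e-300) {
    abort("ICC undefined: no variance in the data",
          class = "femtor_error_undefined_icc")
  }
  denom <- MSR + (k - 1) * MSE + (k / n) * (MSC - MSE)
  if (abs(denom) < 1e-300) {
    abort("ICC undefined: zero denominator", class = "femtor_error_undefined_icc")
  }
  est <- (MSR - MSE) / denom
  alpha <- 1 - conf_level
  # F-based interval with Satterthwaite df (the SPSS/McGraw-Wong procedure)
  a <- (k * est) / (n * (1 - est))
  b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
  if (!is.finite(a) || !is.finite(b)) {   # est == 1: degenerate, exact interval
    ci <- c(1, 1)
  } else {
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    f_l <- qf(1 - alpha / 2, n - 1, v)
    f_u <- qf(1 - alpha / 2, v, n - 1)
    lower <- n * (MSR - f_l * MSE) /
      (f_l * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    upper <- n * (f_u * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * f_u * MSR)
    ci <- c(lower, upper)
  }
  structure(list(estimate = est, conf_low = min(ci[1], est),
                 conf_high = max(ci[2], est),
                 model = model, n = n, k = k,
                 ms = c(MSR = MSR, MSC = MSC, MSE = MSE),
                 conf_level = conf_level),
            class = "fem_icc")
}

#' @export
print.fem_icc <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f (%.3f; %.3f), two-way %s effects, n = %d units, k = %d raters\n",
              x$estimate, x$conf_low, x$conf_high, x$model, x$n, x$k))
  invisible(x)
}

#' Tidy/glance methods for ICC results
#'
#' @param x A `fem_icc` object.
#' @param ... Unused.
#' @return `tidy()`: a one-row tibble with `estimate`, `conf_low`,
#'   `conf_high`, `model`, `n`, `k`. `glance()`: a one-row tibble adding the
#'   ANOVA mean squares.
#' @export
tidy.fem_icc <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, conf_low = x$conf_low,
                 conf_high = x$conf_high, model = x$model, n = x$n, k = x$k)
}

#' @rdname tidy.fem_icc
#' @export
glance.fem_icc <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, conf_low = x$conf_low,
                 conf_high = x$conf_high, model = x$model, n = x$n, k = x$k,
                 ms_rows = unname(x$ms["MSR"]), ms_cols = unname(x$ms["MSC"]),
                 ms_error = unname(x$ms["MSE"]), conf_level = x$conf_level)
}

#' Standard error of measurement
#'
#' SEM = sd(values) * sqrt(1 - ICC), where `values` are all measurements
#' entering the comparison (both columns stacked) and sd is the sample
#' standard deviation.
#'
#' @param values Numeric vector of all measurements in the comparison.
#' @param icc A `fem_icc` object or a plain ICC estimate.
#' @return SEM in the units of `values` (degrees for torsion angles).
#' @export
sem_from_icc <- function(values, icc) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) {
    abort("SEM needs at least 2 values", class = "femtor_error_insufficient")
  }
  est <- if (inherits(icc, "fem_icc")) icc$estimate else as.numeric(icc)
  if (!is.finite(est)) {
    abort("SEM undefined: ICC estimate is not finite",
          class = "femtor_error_undefined_icc")
  }
  sd(values) * sqrt(max(0, 1 - est))
}

#' Paired difference between two measurement sets
#'
#' Classical paired t-test on y - x differences after listwise deletion of
#' incomplete pairs. For modality comparisons pooled over readers, stack both
#' readers' pairs before calling.
#'
#' @param x,y Numeric vectors of paired measurements (same length).
#' @return A one-row tibble: `mean_diff`, `sd_diff`, `t`, `df`, `p_value`,
#'   `n_pairs`, and `degenerate_sd` (`TRUE` when all differences are equal, in
#'   which case `t` and `p_value` are `NA`).
#' @export
paired_difference <- function(x, y) {
  if (length(x) != length(y)) {
    abort("paired vectors must have equal length", class = "femtor_error_parameter")
  }
  keep <- !is.na(x) & !is.na(y)
  d <- y[keep] - x[keep]
  if (length(d) < 2L) {
    abort("paired comparison needs at least 2 complete pairs",
          class = "femtor_error_insufficient")
  }
  m <- mean(d)
  s <- sd(d)
  degenerate <- s < 1e-12
  if (degenerate && abs(m) < 1e-12) {
    # identical vectors: difference is exactly zero
    tstat <- 0
    p <- 1
  } else if (degenerate) {
    tstat <- NA_real_
    p <- NA_real_
  } else {
    ht <- t.test(d)
    tstat <- unname(ht$statistic)
    p <- ht$p.value
  }
  tibble::tibble(mean_diff = m, sd_diff = s, t = tstat,
                 df = length(d) - 1L, p_value = p, n_pairs = length(d),
                 degenerate_sd = degenerate)
}
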