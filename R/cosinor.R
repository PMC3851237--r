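#' Fit a single-component cosinor model to one time series
#'
#' Fits `value = MESOR + A * cos(2*pi*t/period - phi)` by ordinary least
#' squares via the linearization `M + beta*cos(wt) + gamma*sin(wt)`, the
#' standard single-cosinor procedure for fixed-period rhythmometry. The
#' amplitude is `sqrt(beta^2 + gamma^2)` (half the peak-to-trough distance),
#' and the acrophase is the angular position of the peak, reported in positive
#' degrees in `[0, 360)` so that a peak at time `t_peak` maps to
#' `(t_peak mod period) * 360 / period` (15 degrees per hour for a 24-h
#' period). Replicates enter as independent observations, preserving residual
#' degrees of freedom for the zero-amplitude F-test.
#'
#' @param time_h Numeric vector of sampling times (hours).
#' @param value Numeric vector of expression values, same length.
#' @param period_h Fixed rhythm period in hours (default 24).
#' @return An object of class `cosinor_fit`: a list with `mesor`,
#'   `amplitude`, `acrophase_deg`, `period_h`, `r_squared`,
#'   `p_zero_amplitude`, `significance_class` (`"significant"` if p <= 0.05,
#'   `"borderline"` if 0.05 < p < 0.10, else `"none"`), `n`, `flagged`
#'   (TRUE when the fit is exact with nonzero amplitude, so the F-test is
#'   degenerate), and the linear coefficients `beta`, `gamma`.
#' @examples
#' t <- c(1, 4, 10, 16, 22, 28)
#' y <- 1 + 0.5 * cos(2 * pi * (t - 4) / 24)
#' fit_cosinor(t, y) # amplitude 0.5, acrophase 60 degrees
#' @export
fit_cosinor <- function(time_h, value, period_h = 24) {
  if (length(time_h) != length(value))
    stopf("'time_h' and 'value' must have equal length")
  if (any(!is.finite(time_h)) || any(!is.finite(value)))
    stopf("inputs must be finite")
  if (any(time_h < 0)) stopf("'time_h' must be non-negative")
  check_number(period_h, "period_h", 0, Inf, open_min = TRUE)
  n <- length(value)
  if (n < 4 || length(unique(time_h)) < 4)
    stopf("at least 4 distinct time points are required for a cosinor fit")
  omega <- 2 * pi / period_h
  x <- cbind(1, cos(omega * time_h), sin(omega * time_h))
  fit <- stats::lm.fit(x, value)
  cf <- fit$coefficients
  if (anyNA(cf)) stopf("design is rank deficient for period %g h", period_h)
  beta <- unname(cf[2]); gamma <- unname(cf[3])
  mesor <- unname(cf[1])
  amplitude <- sqrt(beta^2 + gamma^2)
  acro <- (atan2(gamma, beta) * 180 / pi) %% 360
  if (360 - acro < 1e-9) acro <- 0  # guard the wrap point against float fuzz
  resid <- value - drop(x %*% cf)
  rss <- sum(resid^2)
  tss <- sum((value - mean(value))^2)
  mss <- max(tss - rss, 0)
  r2 <- if (tss > 0) mss / tss else 0
  zt <- zero_amplitude_test(mss, rss, n)
  p <- zt$p_value
  cls <- if (p <= 0.05) "significant" else if (p < 0.10) "borderline" else "none"
  structure(list(mesor = mesor, amplitude = amplitude, acrophase_deg = acro,
                 period_h = period_h, r_squared = r2, p_zero_amplitude = p,
                 significance_class = cls, n = n, flagged = zt$flagged,
                 beta = beta, gamma = gamma),
            class = "cosinor_fit")
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(
    "cosinor fit (period %g h, n = %d): MESOR %.4g, amplitude %.4g, acrophase %s, R2 %.3f, p = %.4g (%s)%s\n",
    x$period_h, x$n, x$mesor, x$amplitude, acrophase_format(x$acrophase_deg),
    x$r_squared, x$p_zero_amplitude, x$significance_class,
    if (x$flagged) " [exact fit: p degenerate]" else ""))
  invisible(x)
}

#' F-test of the zero-amplitude hypothesis
#'
#' Tests whether the fitted cosine has nonzero amplitude: the two rhythm
#' coefficients together explain `model_ss` of the total sum of squares, and
#' `F = (model_ss / 2) / (resid_ss / (n - 3))` is referred to an F(2, n-3)
#' distribution (upper tail). A rhythm is detected when the amplitude differs
#' from zero, i.e. when p is small.
#'
#' @param model_ss Sum of squares explained by the cosine and sine terms.
#' @param resid_ss Residual sum of squares of the cosinor fit.
#' @param n Number of observations (must exceed 3).
#' @return A list with `statistic`, `p_value`, `df` (length 2), and `flagged`
#'   (TRUE when the residual variance is zero with nonzero amplitude, in
#'   which case the p-value is reported as the smallest representable
#'   positive double).
#' @export
zero_amplitude_test <- function(model_ss, resid_ss, n) {
  n <- check_count(n, "n", 4L)
  if (model_ss < 0 || resid_ss < 0) stopf("sums of squares must be >= 0")
  df2 <- n - 3
  tol <- 1e-10 * (model_ss + resid_ss) + 1e-300
  if (model_ss <= tol)
    return(list(statistic = 0, p_value = 1, df = c(2, df2), flagged = FALSE))
  if (resid_ss <= tol)
    return(list(statistic = Inf, p_value = .Machine$double.xmin,
                df = c(2, df2), flagged = TRUE))
  f <- (model_ss / 2) / (resid_ss / df2)
  list(statistic = f,
       p_value = stats::pf(f, 2, df2, lower.tail = FALSE),
       df = c(2, df2), flagged = FALSE)
}

#' Format an acrophase in degrees and minutes of arc
#'
#' @param acrophase_deg Numeric vector of acrophases in `[0, 360)`.
#' @return Character vector like `"60 deg 42 min"` (with degree and prime
#'   signs); minutes are rounded
#'   and carried into degrees at 60, wrapping at 360.
#' @examples
#' acrophase_format(60.7) # "60 deg 42 min"
#' @export
acrophase_format <- function(acrophase_deg) {
  if (!is.numeric(acrophase_deg) || any(!is.finite(acrophase_deg)) ||
      any(acrophase_deg < 0) || any(acrophase_deg >= 360))
    stopf("'acrophase_deg' must lie in [0, 360)")
  vapply(acrophase_deg, function(a) {
    d <- floor(a)
    m <- round((a - d) * 60)
    if (m == 60) { d <- d + 1; m <- 0 }
    d <- d %% 360
    sprintf("%d\u00b0 %02d\u2032", d, m)
  }, character(1))
}

#' Cosinor rhythm table for a set of time series
#'
#' Fits the 24-h cosinor model to every (gene, condition) series of a
#' time-series table and returns one row per series with the MESOR,
#' amplitude, acrophase (numeric and formatted), R-squared, zero-amplitude
#' p-value and significance class. Series with too few observations yield a
#' row of `NA` fits with status `"no_fit"`.
#'
#' @param series Data frame with columns `gene`, `condition`, `replicate`,
#'   `time_h`, `value` (the time-series table dialect of
#'   [gen_timeseries()]).
#' @param period_h Fixed period in hours (default 24).
#' @param average_replicates If TRUE, replicate values are averaged per time
#'   point before fitting; the default (FALSE) enters replicates as
#'   independent observations.
#' @return Data frame with one row per (gene, condition), ordered by gene
#'   then condition.
#' @seealso [polarogram_table()] for the polar-plot export.
#' @export
rhythm_table <- function(series, period_h = 24, average_replicates = FALSE) {
  need <- c("gene", "condition", "time_h", "value")
  if (!all(need %in% names(series)))
    stopf("'series' must have columns %s", paste(need, collapse = ", "))
  keys <- unique(series[, c("gene", "condition")])
  keys <- keys[order(keys$gene, keys$condition), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- series$gene == keys$gene[i] & series$condition == keys$condition[i]
    tt <- series$time_h[sel]
    vv <- series$value[sel]
    if (average_replicates) {
      vv <- tapply(vv, tt, mean)
      tt <- as.numeric(names(vv))
      vv <- as.numeric(vv)
    }
    fit <- tryCatch(fit_cosinor(tt, vv, period_h), error = function(e) NULL)
    if (is.null(fit)) {
      data.frame(gene = keys$gene[i], condition = keys$condition[i],
                 n = length(vv), mesor = NA_real_, amplitude = NA_real_,
                 acrophase_deg = NA_real_, acrophase = NA_character_,
                 r_squared = NA_real_, p_value = NA_real_,
                 significance = "no_fit", stringsAsFactors = FALSE)
    } else {
      data.frame(gene = keys$gene[i], condition = keys$condition[i],
                 n = fit$n, mesor = fit$mesor, amplitude = fit$amplitude,
                 acrophase_deg = fit$acrophase_deg,
                 acrophase = acrophase_format(fit$acrophase_deg),
                 r_squared = fit$r_squared, p_value = fit$p_zero_amplitude,
                 significance = fit$significance_class,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Polarogram export of a rhythm table
#'
#' Polar-plot coordinates of fitted rhythms: the angle is the acrophase (time
#' of peak, in degrees where 360 degrees = one period) and the radius is the
#' amplitude of the oscillation.
#'
#' @param rhythms A data frame from [rhythm_table()].
#' @return Data frame with columns `gene`, `condition`, `angle_deg`,
#'   `radius`; unfitted series are dropped.
#' @export
polarogram_table <- function(rhythms) {
  ok <- !is.na(rhythms$acrophase_deg)
  data.frame(gene = rhythms$gene[ok], condition = rhythms$condition[ok],
             angle_deg = rhythms$acrophase_deg[ok],
             radius = rhythms$amplitude[ok], stringsAsFactors = FALSE)
}
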