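# The Mu Suppression Index and its sensor-space inferential battery.
#
# MSI = log10(mu-band power in a condition / mu-band power in the
# non-biological-motion baseline). Ratios cancel subject-specific scale
# factors (scalp thickness, impedance); the log makes the statistic symmetric
# around 0, with negative values indicating mu suppression.

#' Mu Suppression Index
#'
#' `log10(cond / baseline)` of mu-band powers. Accepts scalars or aligned
#' vectors (e.g. `band_power` objects, compared location-wise).
#'
#' @param cond_power,baseline_power positive band powers (`band_power`
#'   objects or numerics).
#' @return numeric MSI (log10 units); negative = suppression.
#' @export
#' @examples
#' compute_msi(0.5, 1)   # log10(0.5) = -0.301: suppression
compute_msi <- function(cond_power, baseline_power) {
  p1 <- if (inherits(cond_power, "band_power")) cond_power$power else cond_power
  p0 <- if (inherits(baseline_power, "band_power")) baseline_power$power else baseline_power
  assert_that(all(p1 > 0) && all(p0 > 0), "domain_error",
              "band powers must be strictly positive")
  log10(p1 / p0)
}

#' Assemble an MSI table from band powers
#'
#' @param powers data.frame with columns `subject`, `session`, `condition`,
#'   `location`, `power` (one row per cell).
#' @param baseline_condition label of the non-biological-motion baseline.
#' @return data.frame of class `msi_table` (`subject`, `session`,
#'   `condition`, `location`, `msi`) for every non-baseline condition, with
#'   attribute `baseline_condition`.
#' @export
msi_table <- function(powers, baseline_condition = "balls") {
  assert_that(baseline_condition %in% powers$condition, "baseline_missing",
              sprintf("baseline condition '%s' absent from power table",
                      baseline_condition))
  base <- powers[powers$condition == baseline_condition, ]
  rest <- powers[powers$condition != baseline_condition, ]
  key <- function(d) paste(d$subject, d$session, d$location, sep = "\r")
  b <- stats::setNames(base$power, key(base))
  p0 <- b[key(rest)]
  assert_that(!anyNA(p0), "incomplete_design",
              "baseline power missing for some subject/session/location")
  out <- data.frame(subject = rest$subject, session = rest$session,
                    condition = rest$condition, location = rest$location,
                    msi = compute_msi(rest$power, unname(p0)),
                    stringsAsFactors = FALSE)
  structure(out, class = c("msi_table", "data.frame"),
            baseline_condition = baseline_condition)
}

#' One-sample t-test of MSI against zero
#'
#' Tests whether per-subject mean MSIs differ from zero (suppression or
#' enhancement). Reports t with df = n - 1, two-tailed p, Cohen's d
#' (mean/sd) and the 95% CI of the mean.
#'
#' @param values per-subject MSI means (length >= 2, nonzero variance).
#' @param conf_level confidence level of the interval.
#' @return object of class `msi_test`: list(t, df, p, d, ci, mean, sd, n).
#' @export
msi_ttest_zero <- function(values, conf_level = 0.95) {
  values <- as.numeric(values)
  n <- length(values)
  assert_that(n >= 2, "degenerate_input", "need at least 2 values")
  m <- mean(values); s <- stats::sd(values)
  assert_that(s > 0, "degenerate_input", "zero variance: t is undefined")
  se <- s / sqrt(n)
  t <- m / se
  df <- n - 1
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  q <- stats::qt(1 - (1 - conf_level) / 2, df)
  structure(list(t = t, df = df, p = p, d = m / s,
                 ci = c(m - q * se, m + q * se), mean = m, sd = s, n = n),
            class = "msi_test")
}

#' @export
print.msi_test <- function(x, ...) {
  cat(sprintf("one-sample t vs 0: M = %.4f, t(%d) = %.3f, p = %.4g, d = %.3f, 95%% CI [%.4f, %.4f]\n",
              x$mean, x$df, x$t, x$p, x$d, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Median split into suppressers and non-suppressers
#'
#' Splits subjects by their first-session MSI: the lower half (more negative
#' MSI = stronger suppression) are "suppressers". The split is order-based
#' (stable ascending sort, lower `floor(n/2)` subjects), which for even n
#' without ties coincides with "strictly below the median" and breaks median
#' ties by input order so group sizes stay equal.
#'
#' @param first_session_msi named (or unnamed) per-subject MSI scalars.
#' @return character vector (`"suppresser"` / `"non-suppresser"`) aligned
#'   with the input.
#' @export
median_split <- function(first_session_msi) {
  n <- length(first_session_msi)
  assert_that(n >= 2, "degenerate_input", "need at least 2 subjects")
  ord <- order(first_session_msi)          # stable sort
  labels <- rep("non-suppresser", n)
  labels[ord[seq_len(n %/% 2)]] <- "suppresser"
  names(labels) <- names(first_session_msi)
  labels
}
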