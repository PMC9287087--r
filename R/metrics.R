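#' Community-function metrics on a treatment series
#'
#' The three statistics compared across time periods:
#' \describe{
#'   \item{compensation}{`(SG_E - SG_C) / KR_C`: the fraction of the energy
#'     freed by kangaroo-rat removal taken up by small granivores on the
#'     exclosures.  May be negative or exceed 1.}
#'   \item{total_ratio}{`Etot_E / Etot_C`: overall community function on
#'     exclosures relative to controls; 1 means fully maintained.}
#'   \item{proportion}{within-treatment share of total energy (or biomass)
#'     used by one guild, e.g. `KR_C / Etot_C` or `CB_E / Etot_E`.}
#' }
#' Each returns a *metric series*: one row per census period with columns
#' `period`, `year`, `month`, `mi`, `time` (months since the first census),
#' `period_label`, `value`, `valid`, `reason`.  Census periods with a zero
#' denominator are flagged invalid (`reason = "zero denominator"`) rather
#' than dropped, and are excluded from model fitting downstream.
#'
#' @param ts a `treatment_series` from [aggregate_treatments()].
#' @param basis `"energy"` or `"biomass"`.
#' @param scheme a [period_scheme()] used to label periods.
#' @return a data.frame of class `metric_series` with attributes `metric` and
#'   `basis`.
#' @export
compensation <- function(ts, basis = c("energy", "biomass"),
                         scheme = default_period_scheme()) {
  basis <- match.arg(basis)
  w <- pair_treatments(ts, basis)
  num <- w$sg_E - w$sg_C
  den <- w$kr_C
  metric_series(w, value = ifelse(den > 0, num / den, NA_real_),
                valid = den > 0, metric = "compensation", basis = basis,
                scheme = scheme)
}

#' @rdname compensation
#' @export
total_ratio <- function(ts, basis = c("energy", "biomass"),
                        scheme = default_period_scheme()) {
  basis <- match.arg(basis)
  w <- pair_treatments(ts, basis)
  den <- w$total_C
  metric_series(w, value = ifelse(den > 0, w$total_E / den, NA_real_),
                valid = den > 0, metric = "total_ratio", basis = basis,
                scheme = scheme)
}

#' @rdname compensation
#' @param numerator guild column for the numerator: `"kr"`, `"sg"` or `"cb"`.
#' @param treatment which treatment the proportion is computed within.
#' @details `proportion()` enforces the guild partition: a numerator
#'   exceeding its denominator is an integrity error, never clamped.
#' @export
proportion <- function(ts, numerator = c("kr", "sg", "cb"),
                       treatment = c("control", "exclosure"),
                       basis = c("energy", "biomass"),
                       scheme = default_period_scheme()) {
  numerator <- match.arg(numerator)
  treatment <- match.arg(treatment)
  basis <- match.arg(basis)
  sub <- ts[ts$treatment == treatment, , drop = FALSE]
  num <- sub[[paste0(basis, "_", numerator)]]
  den <- sub[[paste0(basis, "_total")]]
  if (any(num > den * (1 + 1e-9))) {
    stop("proportion numerator exceeds total: guild partition violated")
  }
  valid <- den > 0
  w <- sub[, c("period", "year", "month", "mi")]
  metric_series(w, value = ifelse(valid, num / den, NA_real_), valid = valid,
                metric = paste0("proportion_", numerator, "_", treatment),
                basis = basis, scheme = scheme)
}

#' Trailing moving average of a metric series
#'
#' Mean of the valid values within the `window_months` calendar months ending
#' at (and including) each census month.  Months with no valid value in
#' window are flagged invalid.  Trailing, not centred, so no future data
#' enters the curve; intended for display only, never for inference.
#'
#' @param series a `metric_series`.
#' @param window_months window width in calendar months (default 6).
#' @export
moving_average <- function(series, window_months = 6) {
  if (window_months < 1) stop("window_months must be >= 1")
  out <- series
  v <- ifelse(series$valid, series$value, NA_real_)
  for (i in seq_len(nrow(series))) {
    inwin <- series$mi > series$mi[i] - window_months & series$mi <= series$mi[i]
    vals <- v[inwin]
    vals <- vals[!is.na(vals)]
    if (length(vals)) {
      out$value[i] <- mean(vals)
      out$valid[i] <- TRUE
      out$reason[i] <- ""
    } else {
      out$value[i] <- NA_real_
      out$valid[i] <- FALSE
      out$reason[i] <- "no valid values in window"
    }
  }
  attr(out, "metric") <- paste0(attr(series, "metric"), "_ma", window_months)
  out
}

#' Round-trip a metric series through tidy delimited text
#' @param series a `metric_series`; @param path CSV path.
#' @export
write_metric_series <- function(series, path) {
  df <- as.data.frame(series)
  df$metric <- attr(series, "metric")
  df$basis <- attr(series, "basis")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metric_series
#' @export
read_metric_series <- function(path) {
  df <- read_delim_auto(path)
  metric <- unique(df$metric)[1]
  basis <- unique(df$basis)[1]
  df$metric <- NULL
  df$basis <- NULL
  df$reason[is.na(df$reason)] <- ""
  structure(df, metric = metric, basis = basis,
            class = c("metric_series", "data.frame"))
}

# --- internal helpers -------------------------------------------------------

# widen a treatment series: one row per period with <guild>_<E|C> columns
pair_treatments <- function(ts, basis) {
  cols <- paste0(basis, "_", c("total", "kr", "sg", "cb"))
  E <- ts[ts$treatment == "exclosure", c("period", cols)]
  C <- ts[ts$treatment == "control", c("period", "year", "month", "mi", cols)]
  names(E)[-1] <- paste0(sub(paste0(basis, "_"), "", names(E)[-1]), "_E")
  names(C)[-(1:4)] <- paste0(sub(paste0(basis, "_"), "", names(C)[-(1:4)]), "_C")
  merge(C, E, by = "period")  # inner join: periods with both treatments
}

metric_series <- function(w, value, valid, metric, basis, scheme) {
  reason <- ifelse(valid, "", "zero denominator")
  out <- data.frame(period = w$period, year = w$year, month = w$month,
                    mi = w$mi, stringsAsFactors = FALSE)
  out <- out[order(out$mi), , drop = FALSE]
  o <- order(w$mi)
  out$time <- out$mi - min(out$mi)
  out$period_label <- assign_period(out$mi, scheme)
  out$value <- value[o]
  out$valid <- valid[o]
  out$reason <- reason[o]
  rownames(out) <- NULL
  structure(out, metric = metric, basis = basis,
            class = c("metric_series", "data.frame"))
}
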