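#' Month-resolution time utilities
#'
#' All dates in portalcomp are handled at month resolution: a census bout is
#' identified by its calendar (year, month).  Internally a month is encoded as
#' a single integer index `12 * year + (month - 1)` so that differences between
#' indices are exact month gaps, which is what the continuous-time AR(1)
#' correlation consumes.
#'
#' @param year integer vector of calendar years.
#' @param month integer vector of calendar months (1-12); recycled against
#'   `year`.
#' @return `month_index()` returns an integer vector; `index_to_ym()` the
#'   inverse, a data.frame with columns `year` and `month`.
#' @examples
#' month_index(1988, 3) - month_index(1988, 2)  # 1 month
#' index_to_ym(month_index(2010, 1))
#' @export
month_index <- function(year, month) {
  if (any(!is.finite(year)) || any(!is.finite(month))) {
    stop("year and month must be finite")
  }
  month <- as.integer(month)
  if (any(month < 1L | month > 12L)) stop("month must be in 1..12")
  as.integer(12L * as.integer(year) + (month - 1L))
}

#' @rdname month_index
#' @param mi integer month index as produced by [month_index()].
#' @export
index_to_ym <- function(mi) {
  mi <- as.integer(mi)
  data.frame(year = mi %/% 12L, month = mi %% 12L + 1L)
}

#' Default study window
#'
#' The analysis window of the long-term exclosure comparison: February 1988
#' through January 2020.
#'
#' @return list with integer month indices `start` and `end` (inclusive).
#' @export
default_study_window <- function() {
  list(start = month_index(1988, 2), end = month_index(2020, 1))
}

#' Time-period schemes
#'
#' A time-period scheme partitions the study window into contiguous,
#' non-overlapping, labelled multi-year periods used as the factor in all
#' between-period models.  The default scheme has three periods bracketing the
#' establishment (mid-1997) and sitewide decline (early 2010) of the pocket
#' mouse colonizer:
#' \describe{
#'   \item{P1}{Feb 1988 - Jun 1997, pre-establishment}
#'   \item{P2}{Jul 1997 - Jan 2010, colonizer dominant on exclosures}
#'   \item{P3}{Feb 2010 - Jan 2020, post-decline}
#' }
#'
#' @param labels character vector of period labels.
#' @param starts,ends matching lists/data.frames of `(year, month)` pairs, or
#'   integer month indices.
#' @return a data.frame of class `period_scheme` with columns `label`,
#'   `start`, `end` (integer month indices, inclusive).
#' @export
period_scheme <- function(labels, starts, ends) {
  to_mi <- function(x) {
    if (is.numeric(x)) return(as.integer(x))
    stop("starts/ends must be integer month indices; see month_index()")
  }
  sch <- data.frame(label = as.character(labels),
                    start = to_mi(starts), end = to_mi(ends),
                    stringsAsFactors = FALSE)
  sch <- sch[order(sch$start), ]
  if (any(sch$end < sch$start)) stop("period end precedes start")
  if (nrow(sch) > 1 && any(sch$start[-1] != sch$end[-nrow(sch)] + 1L)) {
    stop("periods must be contiguous and non-overlapping")
  }
  rownames(sch) <- NULL
  class(sch) <- c("period_scheme", "data.frame")
  sch
}

#' @rdname period_scheme
#' @export
default_period_scheme <- function() {
  period_scheme(
    labels = c("P1", "P2", "P3"),
    starts = c(month_index(1988, 2), month_index(1997, 7), month_index(2010, 2)),
    ends   = c(month_index(1997, 6), month_index(2010, 1), month_index(2020, 1))
  )
}

#' Assign census months to time periods
#'
#' Total and single-valued on the scheme's coverage; boundary months belong to
#' the period whose inclusive range contains them (e.g. under the default
#' scheme Jun 1997 is P1, Jul 1997 is P2, Jan 2010 is P2, Feb 2010 is P3).
#'
#' @param mi integer month index vector (see [month_index()]).
#' @param scheme a [period_scheme()]; default [default_period_scheme()].
#' @return factor of period labels, with levels in scheme order.
#' @export
assign_period <- function(mi, scheme = default_period_scheme()) {
  mi <- as.integer(mi)
  idx <- rep(NA_integer_, length(mi))
  for (k in seq_len(nrow(scheme))) {
    idx[mi >= scheme$start[k] & mi <= scheme$end[k]] <- k
  }
  if (anyNA(idx)) {
    bad <- unique(mi[is.na(idx)])
    ym <- index_to_ym(bad[1])
    stop(sprintf("date %d-%02d outside period-scheme coverage", ym$year, ym$month))
  }
  factor(scheme$label[idx], levels = scheme$label)
}
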