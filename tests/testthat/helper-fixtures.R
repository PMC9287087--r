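# Shared fixtures and independent oracles for the test suite.

# -- toy treatment series ----------------------------------------------------
# Build a treatment_series data.frame directly from per-period guild values.
# vals: list of lists with fields period, treatment, kr, sg, cb, other.
make_ts <- function(vals) {
  rows <- lapply(vals, function(v) {
    cb <- if (is.null(v$cb)) 0 else v$cb
    oth <- if (is.null(v$other)) 0 else v$other
    mi <- portalcomp::month_index(1988, 2) + v$period - 1L
    data.frame(period = v$period, year = mi %/% 12L, month = mi %% 12L + 1L,
               mi = mi, treatment = v$treatment, n_plots = 4L,
               energy_total = v$kr + v$sg + oth, energy_kr = v$kr,
               energy_sg = v$sg, energy_cb = cb, energy_other = oth,
               biomass_total = v$kr + v$sg + oth, biomass_kr = v$kr,
               biomass_sg = v$sg, biomass_cb = cb, biomass_other = oth,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("treatment_series", "data.frame")
  out
}

both_treatments <- function(period, kr_C, sg_C, sg_E, cb_C = 0, cb_E = 0,
                            other = 0) {
  list(list(period = period, treatment = "control", kr = kr_C, sg = sg_C,
            cb = cb_C, other = other),
       list(period = period, treatment = "exclosure", kr = 0, sg = sg_E,
            cb = cb_E, other = other))
}

# a compact period scheme: three periods of `months` months from Jan 1990
short_scheme <- function(months = 12) {
  s0 <- portalcomp::month_index(1990, 1)
  portalcomp::period_scheme(
    c("P1", "P2", "P3"),
    c(s0, s0 + months, s0 + 2 * months),
    c(s0 + months - 1, s0 + 2 * months - 1, s0 + 3 * months - 1))
}

short_window <- function(scheme) list(start = min(scheme$start),
                                      end = max(scheme$end))

# -- dense GLS oracle --------------------------------------------------------
# Brute-force generalized least squares under the CAR1 correlation: builds the
# full n x n matrix, inverts it, and evaluates the profiled (RE)ML
# log-likelihood from the generic formulas.  Independent of the whitening
# path used by fit_gls_car1.
gls_dense_oracle <- function(y, X, times, groups, phi, method = "REML") {
  n <- length(y)
  p <- ncol(X)
  R <- portalcomp::car1_correlation(times, phi, groups)
  Ri <- solve(R)
  XtRiX <- t(X) %*% Ri %*% X
  beta <- solve(XtRiX, t(X) %*% Ri %*% y)
  r <- y - X %*% beta
  rss <- as.numeric(t(r) %*% Ri %*% r)
  logdetR <- as.numeric(determinant(R, logarithm = TRUE)$modulus)
  if (method == "REML") {
    sigma2 <- rss / (n - p)
    logdetXtRiX <- as.numeric(determinant(XtRiX, logarithm = TRUE)$modulus)
    loglik <- -0.5 * ((n - p) * log(2 * pi * sigma2) + (n - p) +
                        logdetR + logdetXtRiX)
  } else {
    sigma2 <- rss / n
    loglik <- -0.5 * (n * log(2 * pi * sigma2) + n + logdetR)
  }
  list(beta = as.numeric(beta), sigma2 = sigma2, loglik = loglik,
       vcov = rss / (n - p) * solve(XtRiX))
}

# -- direct metric-level AR(1) simulator -------------------------------------
# Gaussian AR(1) noise around per-period means on contiguous monthly times;
# returns a data.frame ready for fit_gls_car1.
sim_metric_ar1 <- function(n_per = 20, means = c(0.18, 0.58, 0.28),
                           phi = 0.5, sd = 0.1) {
  k <- length(means)
  n <- n_per * k
  z <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  e <- as.numeric(stats::filter(z, phi, method = "recursive",
                                init = stats::rnorm(1, 0, sd)))
  data.frame(
    value = rep(means, each = n_per) + e,
    time = seq_len(n) - 1,
    period_label = factor(rep(paste0("P", seq_len(k)), each = n_per))
  )
}

# quantization tolerance for noise-free generator recovery: one median
# individual's metabolic rate relative to the reference total
median_individual_rate <- function(records) {
  m <- records$mass_g[records$species != portalcomp::SENTINEL_NONE]
  stats::median(5.69 * m^0.75)
}

# widen a treatment series by treatment for test arithmetic
pair_treatments_for_test <- function(ts) {
  C <- ts[ts$treatment == "control", ]
  E <- ts[ts$treatment == "exclosure", ]
  keep <- intersect(C$period, E$period)
  C <- C[match(keep, C$period), ]
  E <- E[match(keep, E$period), ]
  data.frame(period = keep, kr_C = C$energy_kr, sg_C = C$energy_sg,
             total_C = C$energy_total, sg_E = E$energy_sg,
             total_E = E$energy_total, cb_E = E$energy_cb,
             cb_C = C$energy_cb)
}
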