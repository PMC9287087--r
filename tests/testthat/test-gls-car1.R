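# continuous-time AR(1) correlation and profiled GLS

test_that("car1_correlation builds phi^|dt| blocks", {
  expect_equal(car1_correlation(c(3, 7, 9), 0), diag(3))
  R <- car1_correlation(c(0, 1, 2), 0.5)
  expect_equal(R[1, 2], 0.5)
  expect_equal(R[1, 3], 0.25)
  expect_equal(R[2, 3], 0.5)
  expect_equal(diag(R), rep(1, 3))
  # fractional gaps: phi^2.5
  R2 <- car1_correlation(c(0, 2.5), 0.4)
  expect_equal(R2[1, 2], 0.101192885125388, tolerance = 1e-12)
  # group structure zeroes cross-group entries
  R3 <- car1_correlation(c(0, 1, 2, 3), 0.8, groups = c("a", "a", "b", "b"))
  expect_equal(R3[2, 3], 0)
  expect_equal(R3[1, 2], 0.8)
  expect_equal(R3[3, 4], 0.8)
  expect_error(car1_correlation(0:2, 1), "phi")
  expect_error(car1_correlation(0:2, -0.1), "phi")
})

test_that("phi fixed at 0 reproduces ordinary least squares exactly", {
  d <- withr::with_seed(21, sim_metric_ar1(n_per = 15, phi = 0, sd = 0.1))
  fit <- fit_gls_car1(value ~ period_label, d, time = "time",
                      group = "period_label", phi = 0)
  ols <- lm(value ~ period_label, d)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-8)
  expect_equal(unname(vcov(fit)), unname(vcov(ols)), tolerance = 1e-8)
  # and freely estimated phi on independent data stays near zero
  free <- fit_gls_car1(value ~ period_label, d, time = "time",
                       group = "period_label")
  expect_lt(free$phi, 0.25)
  expect_equal(unname(coef(free)), unname(coef(ols)), tolerance = 5e-3)
})

test_that("profiled likelihood matches the dense-matrix oracle on a phi grid", {
  for (seed in 1:2) {
    d <- withr::with_seed(100 + seed,
                          sim_metric_ar1(n_per = 20, phi = 0.6, sd = 0.1))
    X <- model.matrix(~ period_label, d)
    for (method in c("REML", "ML")) {
      for (ph in seq(0, 0.9, by = 0.1)) {
        fit <- fit_gls_car1(value ~ period_label, d, time = "time",
                            group = "period_label", method = method, phi = ph)
        orc <- gls_dense_oracle(d$value, X, d$time, d$period_label, ph, method)
        expect_equal(fit$logLik, orc$loglik, tolerance = 1e-8)
        expect_equal(unname(coef(fit)), orc$beta, tolerance = 1e-8)
        expect_equal(unname(fit$vcov), unname(orc$vcov), tolerance = 1e-8)
      }
    }
  }
})

test_that("estimates agree with nlme::gls under corCAR1", {
  library(nlme)
  d <- withr::with_seed(7, sim_metric_ar1(n_per = 40, phi = 0.5, sd = 0.1))
  fit <- fit_gls_car1(value ~ period_label, d, time = "time",
                      group = "period_label", method = "REML")
  ref <- nlme::gls(value ~ period_label, data = d,
                   correlation = nlme::corCAR1(form = ~ time | period_label),
                   method = "REML")
  phi_ref <- coef(ref$modelStruct$corStruct, unconstrained = FALSE)
  expect_equal(fit$phi, unname(phi_ref), tolerance = 1e-4)
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(fit$vcov))), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-4)
  expect_equal(fit$logLik, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("likelihood depends only on within-group time gaps", {
  d <- withr::with_seed(31, sim_metric_ar1(n_per = 12, phi = 0.5, sd = 0.1))
  fit1 <- fit_gls_car1(value ~ period_label, d, time = "time",
                       group = "period_label")
  d2 <- d
  shift <- c(P1 = 0, P2 = 1000, P3 = -500)
  d2$time <- d2$time + shift[as.character(d2$period_label)]
  fit2 <- fit_gls_car1(value ~ period_label, d2, time = "time",
                       group = "period_label")
  expect_equal(fit1$logLik, fit2$logLik, tolerance = 1e-10)
  expect_equal(coef(fit1), coef(fit2), tolerance = 1e-10)
  expect_equal(fit1$phi, fit2$phi, tolerance = 1e-8)
})

test_that("missed censuses (irregular gaps) are handled through phi^gap", {
  d <- withr::with_seed(17, sim_metric_ar1(n_per = 30, phi = 0.7, sd = 0.1))
  d <- d[-c(5, 6, 17, 44, 45, 46, 70), ]   # knock out some months
  fit <- fit_gls_car1(value ~ period_label, d, time = "time",
                      group = "period_label")
  X <- model.matrix(~ period_label, d)
  orc <- gls_dense_oracle(d$value, X, d$time, d$period_label, fit$phi, "REML")
  expect_equal(fit$logLik, orc$loglik, tolerance = 1e-8)
})

test_that("degenerate designs raise errors", {
  d <- sim_metric_ar1(n_per = 10)
  d$dup <- d$period_label   # aliased factor
  expect_error(fit_gls_car1(value ~ period_label + dup, d, time = "time"),
               "rank")
  expect_error(fit_gls_car1(value ~ period_label, d[1:4, ], time = "time"),
               "observations")
})

test_that("period means are recovered within Monte-Carlo error", {
  truth <- c(0.18, 0.58, 0.28)
  nrep <- 40
  est <- matrix(NA_real_, nrep, 3)
  withr::with_seed(555, {
    for (r in seq_len(nrep)) {
      d <- sim_metric_ar1(n_per = 50, means = truth, phi = 0.5, sd = 0.1)
      fit <- fit_gls_car1(value ~ period_label, d, time = "time",
                          group = "period_label")
      est[r, ] <- marginal_means(fit, "period_label")$means$estimate
    }
  })
  mc_se <- apply(est, 2, sd) / sqrt(nrep)
  expect_true(all(abs(colMeans(est) - truth) <= 3 * mc_se + 1e-12))
})

test_that("AIC comparison selects the generating correlation structure", {
  # strong autocorrelation -> CAR1 wins
  d <- withr::with_seed(88, sim_metric_ar1(n_per = 40, phi = 0.8, sd = 0.1))
  tab <- compare_correlation_structures(value ~ period_label, d,
                                        time = "time", group = "period_label")
  expect_equal(tab$structure[tab$selected], "car1")
  expect_equal(tab$npar, c(4, 5))
  # independence recovered in most replicates
  hits <- withr::with_seed(303, {
    vapply(1:30, function(r) {
      d0 <- sim_metric_ar1(n_per = 20, phi = 0, sd = 0.1)
      t0 <- compare_correlation_structures(value ~ period_label, d0,
                                           time = "time",
                                           group = "period_label")
      t0$structure[t0$selected] == "independence"
    }, logical(1))
  })
  expect_gte(mean(hits), 0.8)
  expect_error(compare_correlation_structures(value ~ 1, d[1:4, ],
                                              time = "time"),
               "insufficient")
})
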