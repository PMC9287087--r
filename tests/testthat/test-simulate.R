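# synthetic community generator

test_that("ground_truth closed forms", {
  cfg <- scenario_config(scheme = short_scheme(6))
  gt <- ground_truth(cfg)
  expect_equal(gt$total_ratio, 1 - cfg$q * (1 - cfg$comp), tolerance = 1e-12)
  # spot values: q = 0.92, c = 0.18 -> 1 - 0.92*0.82 = 0.2456
  expect_equal(gt$total_ratio[1], 0.2456, tolerance = 1e-12)
  expect_equal(gt$prop_kr_control, cfg$q)
  # full compensation or nothing removed both give ratio 1
  cfg2 <- scenario_config(scheme = short_scheme(6), comp = c(1, 1, 1))
  expect_equal(ground_truth(cfg2)$total_ratio, rep(1, 3))
  cfg3 <- scenario_config(scheme = short_scheme(6), q = c(0, 0, 0),
                          cb_ctrl = c(0, 0.1, 0.005))
  expect_equal(ground_truth(cfg3)$total_ratio, rep(1, 3))
})

test_that("impossible share configurations are rejected", {
  expect_error(scenario_config(scheme = short_scheme(6), q = c(1.2, 0.7, 0.7)),
               "\\[0, 1\\]")
  expect_error(scenario_config(scheme = short_scheme(6),
                               cb_ctrl = c(0, 0.5, 0)),
               "control share exceeds")
  expect_error(scenario_config(scheme = short_scheme(6),
                               cb_excl = c(0, 0.999, 0.26)),
               "exclosure share exceeds")
  expect_error(scenario_config(scheme = short_scheme(6), noise_phi = 1),
               "noise_phi")
  expect_error(scenario_config(scheme = short_scheme(6), q = c(0.9, 0.9)),
               "one value per period")
})

test_that("simulation is deterministic under the seed, byte for byte", {
  cfg <- scenario_config(scheme = short_scheme(6), seed = 77)
  s1 <- simulate_scenario(cfg)
  s2 <- simulate_scenario(cfg)
  expect_identical(s1$records, s2$records)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_captures(s1$records, f1)
  write_captures(s2$records, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # and does not disturb the caller's RNG
  set.seed(1)
  a <- runif(1)
  set.seed(1)
  invisible(simulate_scenario(cfg))
  expect_identical(runif(1), a)
})

test_that("colonizer event 'never' leaves the CB columns identically zero", {
  cfg <- scenario_config(scheme = short_scheme(6), cb_event = "never",
                         seed = 12)
  sim <- simulate_scenario(cfg)
  expect_false(any(sim$records$species == cfg$focal_species))
  ts <- aggregate_treatments(sim$records, cfg$plots)
  expect_equal(ts$energy_cb, rep(0, nrow(ts)))
})

test_that("the colonizer is absent before its event month", {
  sch <- short_scheme(12)  # periods start Jan 1990
  ev <- c(1990, 7)
  cfg <- scenario_config(scheme = sch, cb_event = ev, seed = 13,
                         miss_prob = 0)
  sim <- simulate_scenario(cfg)
  pb <- sim$records[sim$records$species == "PB", ]
  expect_true(all(pb$mi >= month_index(ev[1], ev[2])))
  expect_gt(nrow(pb), 0)
  # establishment detection finds a post-event census on all exclosures
  excl <- cfg$plots$plot[cfg$plots$treatment == "exclosure"]
  est <- detect_establishment(sim$records, "PB", excl)
  expect_false(is.na(est))
  first_mi <- min(sim$records$mi[sim$records$period == est])
  expect_gte(first_mi, month_index(ev[1], ev[2]))
})

test_that("zero-noise simulation reproduces ground truth to quantization tolerance", {
  cfg <- scenario_config(scheme = short_scheme(12), noise_sd = 0, mass_sd = 0,
                         miss_prob = 0, seed = 21)
  sim <- simulate_scenario(cfg)
  ts <- aggregate_treatments(sim$records, cfg$plots)
  comp <- compensation(ts, scheme = cfg$scheme)
  ratio <- total_ratio(ts, scheme = cfg$scheme)
  gt <- ground_truth(cfg)
  med_b <- median_individual_rate(sim$records)
  wide <- pair_treatments_for_test(ts)
  for (k in seq_len(nrow(gt))) {
    lab <- gt$period_label[k]
    kr_c <- mean(wide$kr_C[comp$period_label == lab])
    tot_c <- mean(wide$total_C[comp$period_label == lab])
    expect_lt(abs(mean(comp$value[comp$period_label == lab]) -
                    gt$compensation[k]),
              med_b / kr_c)
    expect_lt(abs(mean(ratio$value[ratio$period_label == lab]) -
                    gt$total_ratio[k]),
              2 * med_b / tot_c)
  }
})

test_that("poisson quantization draws plausible communities", {
  cfg <- scenario_config(scheme = short_scheme(6), quantization = "poisson",
                         seed = 31)
  sim <- simulate_scenario(cfg)
  ts <- aggregate_treatments(sim$records, cfg$plots)
  comp <- compensation(ts, scheme = cfg$scheme)
  expect_gt(nrow(sim$records), 100)
  expect_true(all(is.finite(comp$value[comp$valid])))
})

test_that("missed censuses thin the month grid but keep period ids sequential", {
  cfg <- scenario_config(scheme = short_scheme(12), miss_prob = 0.2, seed = 41)
  sim <- simulate_scenario(cfg)
  months <- unique(sim$records$mi)
  expect_lt(length(months), 36)
  per <- unique(sim$records$period)
  expect_equal(sort(per), seq_along(per))
})

test_that("scenario files round-trip through versioned JSON", {
  cfg <- scenario_config(scheme = short_scheme(6), seed = 8,
                         cb_event = c(1990, 4))
  f <- withr::local_tempfile(fileext = ".json")
  write_scenario(cfg, f)
  back <- read_scenario(f)
  expect_equal(back$q, cfg$q)
  expect_equal(back$seed, cfg$seed)
  expect_identical(simulate_scenario(back)$records,
                   simulate_scenario(cfg)$records)
  # version guard
  raw <- jsonlite::read_json(f, simplifyVector = TRUE)
  raw$schema_version <- 99
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(raw, f2, auto_unbox = TRUE, digits = NA)
  expect_error(read_scenario(f2), "schema version")
})

test_that("stronger simulated autocorrelation widens estimated intervals", {
  widths <- sapply(c(0, 0.4, 0.8), function(ph) {
    mean(withr::with_seed(1000 + round(100 * ph), {
      vapply(1:100, function(r) {
        d <- sim_metric_ar1(n_per = 20, phi = ph, sd = 0.1)
        fit <- fit_gls_car1(value ~ period_label, d, time = "time",
                            group = "period_label")
        mm <- marginal_means(fit, "period_label")
        mean(mm$means$upper - mm$means$lower)
      }, numeric(1))
    }))
  })
  expect_true(all(diff(widths) > 0))
})
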