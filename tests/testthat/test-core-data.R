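# core data model: ingestion, window filtering, plot selection, period
# assignment, establishment detection

test_that("read_captures ingests well-formed tables and flags problems", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("period,year,month,plot,species,wgt",
               "1,1990,1,4,DM,41.5",
               "1,1990,1,11,PP,",
               "2,1990,2,4,ZZ,12"), f)
  expect_message(rec <- read_captures(f), "outside registry")
  expect_equal(nrow(rec), 3)
  expect_true(is.na(rec$mass_g[2]))          # empty mass -> flagged missing
  expect_false(rec$known[3])                 # unknown species retained, flagged
  diag <- attr(rec, "diagnostics")
  expect_equal(diag$n_unknown_species, 1)
  expect_equal(diag$unknown_codes, "ZZ")

  # tab-delimited accepted
  ftab <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("period\tyear\tmonth\tplot\tspecies\twgt",
               "1\t1990\t1\t4\tDM\t41.5"), ftab)
  expect_equal(nrow(read_captures(ftab)), 1)

  # missing required column named in the error
  fbad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("period,year,month,species,wgt", "1,1990,1,DM,41.5"), fbad)
  expect_error(read_captures(fbad), "'plot'")

  # malformed month dropped and reported
  fmal <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("period,year,month,plot,species,wgt",
               "1,1990,13,4,DM,41.5", "1,1990,2,4,DM,40"), fmal)
  expect_message(rec2 <- read_captures(fmal), "malformed")
  expect_equal(nrow(rec2), 1)
  expect_equal(attr(rec2, "diagnostics")$bad_rows, 1L)
})

test_that("capture read/write round trip preserves records", {
  sim <- simulate_scenario(scenario_config(scheme = short_scheme(6), seed = 9))
  f <- withr::local_tempfile(fileext = ".csv")
  write_captures(sim$records, f)
  back <- read_captures(f)
  expect_equal(nrow(back), nrow(sim$records))
  expect_equal(back$species, sim$records$species)
  expect_equal(back$plot, sim$records$plot)
  expect_equal(back$mass_g, sim$records$mass_g, tolerance = 1e-12)
})

test_that("filter_window keeps the inclusive study window and ordering", {
  rec <- data.frame(period = 1:4, year = c(1988, 1988, 2020, 2020),
                    month = c(1, 2, 1, 2), plot = 1, species = "DM",
                    mass_g = 40)
  rec$mi <- month_index(rec$year, rec$month)
  kept <- filter_window(rec)
  expect_equal(kept$period, 2:3)     # Feb 1988 and Jan 2020 kept, ends dropped
  expect_equal(nrow(filter_window(rec[0, ])), 0)
  expect_equal(filter_window(rec, min(rec$mi), max(rec$mi)), rec)
  expect_error(filter_window(rec, 10, 5), "start after end")
})

test_that("select_plots balances treatments, is seed-reproducible, and honours overrides", {
  cand <- default_plot_candidates()   # 4 controls + 5 exclosures
  s1 <- select_plots(cand, 4, seed = 11)
  s2 <- select_plots(cand, 4, seed = 11)
  expect_identical(s1, s2)
  expect_equal(as.vector(table(s1$treatment)), c(4, 4))
  # controls taken as-is when exactly four available
  expect_setequal(s1$plot[s1$treatment == "control"],
                  cand$plot[cand$treatment == "control"])
  # a different seed can (and here does) pick a different exclosure subset
  s3 <- select_plots(cand, 4, seed = 12)
  expect_true(is.data.frame(s3) && nrow(s3) == 8)

  ov <- select_plots(cand, 4, seed = 1, override = cand$plot[c(1:4, 5:8)])
  expect_setequal(ov$plot, cand$plot[1:8])

  few <- plot_table(1:7, c(rep("control", 4), rep("exclosure", 3)))
  expect_error(select_plots(few, 4), "3 exclosure")
})

test_that("select_plots does not disturb the caller's RNG stream", {
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(select_plots(default_plot_candidates(), 4, seed = 5))
  expect_identical(runif(1), a)
})

test_that("assign_period handles boundaries and errors outside coverage", {
  sch <- default_period_scheme()
  expect_equal(as.character(assign_period(month_index(1988, 2), sch)), "P1")
  expect_equal(as.character(assign_period(month_index(1997, 6), sch)), "P1")
  expect_equal(as.character(assign_period(month_index(1997, 7), sch)), "P2")
  expect_equal(as.character(assign_period(month_index(2010, 1), sch)), "P2")
  expect_equal(as.character(assign_period(month_index(2010, 2), sch)), "P3")
  expect_equal(as.character(assign_period(month_index(2020, 1), sch)), "P3")
  expect_error(assign_period(month_index(2025, 3), sch), "outside")
})

test_that("the default periods partition the study window exactly", {
  sch <- default_period_scheme()
  win <- default_study_window()
  all_mi <- seq(win$start, win$end)
  lab <- assign_period(all_mi, sch)     # total: no error anywhere
  counts <- table(lab)
  expect_equal(sum(counts), length(all_mi))
  # contiguity: each period's months form one run
  expect_equal(as.integer(counts),
               as.integer(sch$end - sch$start + 1))
})

test_that("detect_establishment finds the first all-exclosure census", {
  rec <- data.frame(
    period = c(5, 6, 7, 7, 8, 8),
    plot = c(1, 1, 1, 2, 1, 2),
    species = "PB", stringsAsFactors = FALSE)
  expect_equal(detect_establishment(rec, "PB", c(1, 2)), 7)
  expect_true(is.na(detect_establishment(rec, "PB", c(1, 2, 3))))  # never on 3
  expect_equal(detect_establishment(rec, "PB", 1), 5)  # all plots from start
  expect_error(detect_establishment(rec, "PB", integer(0)), "empty")
})

test_that("impute_mass fills species means and reports counts", {
  rec <- data.frame(period = 1, year = 1990, month = 1, plot = 1,
                    species = c("DM", "DM", "DM", "PF"),
                    mass_g = c(40, 44, NA, NA))
  rec$mi <- month_index(rec$year, rec$month)
  rec$known <- TRUE
  expect_message(out <- impute_mass(rec), "imputed 2")
  expect_equal(out$mass_g[3], 42)                     # mean of observed DM
  reg <- default_species_registry()
  expect_equal(out$mass_g[4], reg$mean_mass_g[reg$species == "PF"])
  expect_equal(attr(out, "n_imputed"), 2L)
})
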