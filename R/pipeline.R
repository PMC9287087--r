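#' Run configuration for the end-to-end analysis
#'
#' Exactly one of `scenario` (a [scenario_config()] or scenario JSON path) or
#' the three input paths (`captures`, `plots`, `registry`) must be supplied.
#'
#' @param captures,plots,registry paths to the capture table, plot-treatment
#'   table and species registry (delimited text).
#' @param scenario a [scenario_config()] object or path to a scenario file.
#' @param window study window as `list(start =, end =)` month indices.
#' @param scheme a [period_scheme()].
#' @param etot_scope `"all"` or `"granivores"` (see [aggregate_treatments()]).
#' @param basis `"energy"`, `"biomass"`, or `"both"`.
#' @param n_per_treatment,plot_seed,plot_override plot-selection controls
#'   (see [select_plots()]).
#' @param focal_species colonizer species code.
#' @param cb_periods period labels over which the colonizer proportion is
#'   modelled (default: all periods after the first).
#' @param method `"REML"` or `"ML"` for the GLS fits.
#' @param var_by_group per-period residual variances in the GLS fits
#'   (default `TRUE`; see [fit_gls_car1()]).
#' @param adjust contrast adjustment (see [marginal_means()]).
#' @param out_dir output directory for tables, plot and manifest; `NULL`
#'   disables file output.
#' @return list of class `run_config`.
#' @export
run_config <- function(captures = NULL, plots = NULL, registry = NULL,
                       scenario = NULL,
                       window = default_study_window(),
                       scheme = default_period_scheme(),
                       etot_scope = c("all", "granivores"),
                       basis = c("energy", "biomass", "both"),
                       n_per_treatment = 4, plot_seed = 1988,
                       plot_override = NULL,
                       focal_species = "PB",
                       cb_periods = NULL,
                       method = c("REML", "ML"),
                       var_by_group = TRUE,
                       adjust = c("tukey", "none", "bonferroni"),
                       out_dir = NULL) {
  has_paths <- !is.null(captures)
  has_scen <- !is.null(scenario)
  if (has_paths == has_scen) {
    stop("provide exactly one of capture-table paths or a scenario")
  }
  cfg <- list(captures = captures, plots = plots, registry = registry,
              scenario = scenario, window = window, scheme = scheme,
              etot_scope = match.arg(etot_scope), basis = match.arg(basis),
              n_per_treatment = n_per_treatment, plot_seed = plot_seed,
              plot_override = plot_override, focal_species = focal_species,
              cb_periods = cb_periods, method = match.arg(method),
              var_by_group = isTRUE(var_by_group),
              adjust = match.arg(adjust), out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full compensation analysis
#'
#' Ingest (or simulate), aggregate, compute metrics, fit the four models
#' (compensation GLS, total-ratio GLS, kangaroo-rat control-share GLM,
#' colonizer-share GLM with a treatment factor), and summarize period-level
#' marginal means and contrasts.  With `out_dir` set, writes tidy metric and
#' summary tables, a four-panel figure, and a machine-readable run manifest.
#'
#' @param config a [run_config()].
#' @return list of class `portalcomp_report` with elements `series`
#'   (treatment series), `metrics`, `fits`, `summaries`, `truth` (for
#'   scenario runs), `diagnostics`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- "ingest"
  res <- tryCatch({
    ing <- pipeline_ingest(config)
    stage <- "energetics"
    ts <- aggregate_treatments(ing$records, ing$plots, ing$registry,
                               focal_species = config$focal_species,
                               etot_scope = config$etot_scope)
    stage <- "metrics"
    bases <- if (config$basis == "both") c("energy", "biomass") else config$basis
    metrics <- list()
    fits <- list()
    summaries <- list()
    for (b in bases) {
      m <- pipeline_metrics(ts, b, config)
      metrics[[b]] <- m
      stage <- "inference"
      f <- pipeline_fits(m, config)
      fits[[b]] <- f$fits
      summaries[[b]] <- f$summaries
      stage <- "metrics"
    }
    stage <- "report"
    report <- structure(list(series = ts, metrics = metrics, fits = fits,
                             summaries = summaries, truth = ing$truth,
                             diagnostics = ing$diagnostics, config = config),
                        class = "portalcomp_report")
    if (!is.null(config$out_dir)) write_report(report, config$out_dir)
    report
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  res
}

pipeline_ingest <- function(config) {
  if (!is.null(config$scenario)) {
    scen <- config$scenario
    if (is.character(scen)) scen <- read_scenario(scen)
    sim <- simulate_scenario(scen)
    rec <- filter_window(sim$records, config$window$start, config$window$end)
    list(records = rec, plots = scen$plots, registry = scen$registry,
         truth = sim$truth, diagnostics = list(source = "scenario",
                                               seed = scen$seed))
  } else {
    registry <- if (is.null(config$registry)) default_species_registry()
                else read_species_registry(config$registry)
    candidates <- if (is.null(config$plots)) default_plot_candidates()
                  else read_plot_table(config$plots)
    plots <- select_plots(candidates, config$n_per_treatment,
                          seed = config$plot_seed,
                          override = config$plot_override)
    rec <- read_captures(config$captures, registry)
    rec <- filter_window(rec, config$window$start, config$window$end)
    rec <- impute_mass(rec, registry)
    list(records = rec, plots = plots, registry = registry, truth = NULL,
         diagnostics = c(attr(rec, "diagnostics"),
                         list(source = "files",
                              plot_seed = attr(plots, "seed"),
                              n_imputed = attr(rec, "n_imputed"))))
  }
}

pipeline_metrics <- function(ts, basis, config) {
  list(
    compensation = compensation(ts, basis, config$scheme),
    total_ratio = total_ratio(ts, basis, config$scheme),
    prop_kr_control = proportion(ts, "kr", "control", basis, config$scheme),
    prop_cb_exclosure = proportion(ts, "cb", "exclosure", basis, config$scheme),
    prop_cb_control = proportion(ts, "cb", "control", basis, config$scheme)
  )
}

pipeline_fits <- function(m, config) {
  valid_df <- function(ms) as.data.frame(ms[ms$valid, , drop = FALSE])
  fits <- list()
  summaries <- list()

  for (nm in c("compensation", "total_ratio")) {
    d <- valid_df(m[[nm]])
    d$period_label <- droplevels(d$period_label)
    fits[[nm]] <- fit_gls_car1(value ~ period_label, d, time = "time",
                               group = "period_label", method = config$method,
                               var_by_group = config$var_by_group)
    summaries[[nm]] <- marginal_means(fits[[nm]], "period_label",
                                      adjust = config$adjust)
  }

  d <- valid_df(m$prop_kr_control)
  d$period_label <- droplevels(d$period_label)
  fits$prop_kr_control <- fit_proportion_glm(value ~ period_label, d)
  summaries$prop_kr_control <- marginal_means(fits$prop_kr_control,
                                              "period_label",
                                              adjust = config$adjust)

  # colonizer model: both treatments, restricted to post-establishment periods
  cb_periods <- config$cb_periods
  if (is.null(cb_periods)) cb_periods <- config$scheme$label[-1]
  dE <- valid_df(m$prop_cb_exclosure)
  dE$treatment <- "exclosure"
  dC <- valid_df(m$prop_cb_control)
  dC$treatment <- "control"
  d <- rbind(dE, dC)
  d <- d[d$period_label %in% cb_periods, , drop = FALSE]
  d$period_label <- droplevels(d$period_label)
  d$treatment <- factor(d$treatment, c("control", "exclosure"))
  if (nrow(d) > 0 && nlevels(d$period_label) >= 2) {
    fits$prop_cb <- fit_proportion_glm(value ~ period_label + treatment, d)
    summaries$prop_cb_period <- marginal_means(fits$prop_cb, "period_label",
                                               adjust = config$adjust)
    summaries$prop_cb_treatment <- marginal_means(fits$prop_cb, "treatment",
                                                  adjust = config$adjust)
  }
  list(fits = fits, summaries = summaries)
}

#' @export
print.portalcomp_report <- function(x, ...) {
  cat("portalcomp analysis report\n")
  for (b in names(x$summaries)) {
    cat(sprintf("\n== basis: %s ==\n", b))
    for (nm in names(x$summaries[[b]])) {
      cat(sprintf("\n-- %s --\n", nm))
      print(x$summaries[[b]][[nm]])
    }
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- report$config
  for (b in names(report$metrics)) {
    for (nm in names(report$metrics[[b]])) {
      write_metric_series(report$metrics[[b]][[nm]],
                          file.path(out_dir, sprintf("metric_%s_%s.csv", b, nm)))
    }
    for (nm in names(report$summaries[[b]])) {
      write_marginal_summary(report$summaries[[b]][[nm]],
        file.path(out_dir, sprintf("means_%s_%s.csv", b, nm)),
        file.path(out_dir, sprintf("contrasts_%s_%s.csv", b, nm)))
    }
    fit_tab <- do.call(rbind, lapply(names(report$fits[[b]]), function(nm) {
      f <- report$fits[[b]][[nm]]
      data.frame(model = nm,
                 family = if (inherits(f, "car1_fit")) "gaussian_car1"
                          else "quasibinomial_logit",
                 phi = if (inherits(f, "car1_fit")) f$phi else NA_real_,
                 dispersion_or_sigma2 = if (inherits(f, "car1_fit")) f$sigma2
                                        else f$dispersion,
                 logLik_or_AIC = if (inherits(f, "car1_fit")) f$logLik else NA_real_,
                 n = f$n)
    }))
    utils::write.csv(fit_tab, file.path(out_dir, sprintf("fits_%s.csv", b)),
                     row.names = FALSE, quote = FALSE)
  }
  write_treatment_series(report$series, file.path(out_dir, "treatment_series.csv"))
  plot_file <- file.path(out_dir, "figure_overview.png")
  try(plot_report(report, plot_file), silent = TRUE)
  manifest <- list(
    package = "portalcomp",
    version = as.character(utils::packageVersion("portalcomp")),
    r_version = as.character(getRversion()),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = serialize_run_config(cfg)
  )
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest$config_hash <- as.character(tools::md5sum(mpath))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(out_dir)
}

serialize_run_config <- function(cfg) {
  out <- unclass(cfg)
  out$scheme <- as.data.frame(out$scheme)
  if (inherits(out$scenario, "scenario_config")) {
    sc <- unclass(out$scenario)
    sc$scheme <- as.data.frame(sc$scheme)
    sc$plots <- as.data.frame(sc$plots)
    sc$registry <- as.data.frame(sc$registry)
    out$scenario <- sc
  }
  out
}

#' Rebuild a run configuration from a written manifest
#'
#' The manifest alone suffices to re-run a scenario analysis.
#'
#' @param path path to a `manifest.json` written by [run_pipeline()].
#' @export
read_manifest_config <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- man$config
  # NULL config fields serialize as {} and read back as empty lists
  raw <- lapply(raw, function(x) if (length(x) == 0) NULL else x)
  scen <- NULL
  if (!is.null(raw$scenario) && is.list(raw$scenario)) {
    s <- raw$scenario
    scen <- scenario_config(
      scheme = period_scheme(s$scheme$label, s$scheme$start, s$scheme$end),
      plots = plot_table(s$plots$plot, s$plots$treatment),
      q = s$q, comp = s$comp, cb_excl = s$cb_excl, cb_ctrl = s$cb_ctrl,
      sg_frac = s$sg_frac, E0 = s$E0, noise_sd = s$noise_sd,
      noise_phi = s$noise_phi, mass_sd = s$mass_sd, miss_prob = s$miss_prob,
      cb_event = if (identical(s$cb_event, "never")) "never"
                 else as.integer(s$cb_event),
      cb_arrival_excl = s$cb_arrival_excl, cb_arrival_ctrl = s$cb_arrival_ctrl,
      quantization = s$quantization,
      registry = species_registry(s$registry$species, s$registry$guild,
                                  s$registry$mean_mass_g, s$registry$weight),
      focal_species = s$focal_species, seed = s$seed)
  }
  run_config(
    captures = raw$captures, plots = raw$plots, registry = raw$registry,
    scenario = scen,
    window = list(start = raw$window$start, end = raw$window$end),
    scheme = period_scheme(raw$scheme$label, raw$scheme$start, raw$scheme$end),
    etot_scope = raw$etot_scope, basis = raw$basis,
    n_per_treatment = raw$n_per_treatment, plot_seed = raw$plot_seed,
    plot_override = raw$plot_override, focal_species = raw$focal_species,
    cb_periods = raw$cb_periods, method = raw$method,
    var_by_group = isTRUE(raw$var_by_group), adjust = raw$adjust,
    out_dir = raw$out_dir
  )
}

#' Four-panel overview figure
#'
#' Renders (a) the total energy ratio, (b) the 6-month moving average of
#' compensation, (c) the kangaroo-rat control share and (d) the colonizer
#' shares on both treatments, each with period-level estimated means and 95%
#' interval bands, to a PNG file.
#'
#' @param report a `portalcomp_report`.
#' @param file output PNG path.
#' @param basis which basis to draw (default the first available).
#' @export
plot_report <- function(report, file, basis = names(report$metrics)[1]) {
  m <- report$metrics[[basis]]
  s <- report$summaries[[basis]]
  grDevices::png(file, width = 1200, height = 900, res = 120)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mfrow = c(2, 2), mar = c(3.5, 3.8, 2, 1), mgp = c(2.2, 0.7, 0))
  on.exit(graphics::par(op), add = TRUE)
  scheme <- report$config$scheme

  panel <- function(ms, summ, main, ylab, col = "grey25") {
    d <- ms[ms$valid, ]
    yr <- d$year + (d$month - 1) / 12
    graphics::plot(yr, d$value, type = "l", col = col, xlab = "year",
                   ylab = ylab, main = main, cex.main = 0.95)
    graphics::abline(v = (scheme$start[-1] %/% 12), lty = 3)
    if (!is.null(summ)) {
      for (i in seq_len(nrow(summ$means))) {
        lab <- summ$means$level[i]
        k <- match(lab, scheme$label)
        if (is.na(k)) next
        x0 <- scheme$start[k] %/% 12
        x1 <- scheme$end[k] %/% 12 + 1
        graphics::rect(x0, summ$means$lower[i], x1, summ$means$upper[i],
                       col = grDevices::adjustcolor("steelblue", 0.25),
                       border = NA)
        graphics::segments(x0, summ$means$estimate[i], x1,
                           summ$means$estimate[i], col = "steelblue4", lwd = 2)
      }
    }
  }
  panel(m$total_ratio, s$total_ratio, "(a) total energy ratio E:C", "ratio")
  panel(moving_average(m$compensation, 6), s$compensation,
        "(b) compensation, 6-month moving average", "compensation")
  panel(m$prop_kr_control, s$prop_kr_control,
        "(c) kangaroo-rat share of control energy", "proportion")
  dE <- m$prop_cb_exclosure[m$prop_cb_exclosure$valid, ]
  dC <- m$prop_cb_control[m$prop_cb_control$valid, ]
  graphics::plot(dE$year + (dE$month - 1) / 12, dE$value, type = "l",
                 col = "steelblue4", xlab = "year", ylab = "proportion",
                 main = "(d) colonizer share (blue: exclosure, gold: control)",
                 cex.main = 0.95)
  graphics::lines(dC$year + (dC$month - 1) / 12, dC$value, col = "goldenrod3")
  graphics::abline(v = (scheme$start[-1] %/% 12), lty = 3)
  invisible(file)
}

#' Published period-level estimates used for reproduction checks
#'
#' Point estimates (percent) reported for the archived-study analysis:
#' compensation, total energy ratio, kangaroo-rat control share, and
#' colonizer shares on the two treatments, per time period.
#'
#' @return data.frame of reference values (percent; `NA` where the quantity
#'   was not reported for a period).
#' @export
paper_reference_estimates <- function() {
  data.frame(
    period_label = c("P1", "P2", "P3"),
    compensation = c(18, 58, 28),
    total_ratio = c(30, 71, 50),
    prop_kr_control = c(92, 70, 70),
    prop_cb_exclosure = c(NA, 72, 26),
    prop_cb_control = c(NA, 11, 0),
    stringsAsFactors = FALSE
  )
}

#' Reproduce the archived-study analysis
#'
#' Runs the full pipeline on a locally downloaded copy of the archived
#' capture data (Zenodo deposits 10.5281/zenodo.5544361 /
#' 10.5281/zenodo.5539880) and prints estimated period means side by side
#' with the published values.  The data directory must contain
#' `captures.csv`, `plots.csv` and `species.csv` in the package's table
#' dialects (see [read_captures()]); re-exporting the deposit into this
#' layout is a one-time manual step.  Requires no network here: only local
#' files.
#'
#' @param data_dir directory with the three input files.
#' @param config optional [run_config()] overriding the defaults (its input
#'   paths are replaced by the `data_dir` files).
#' @return data.frame comparison table (estimates vs published values,
#'   percent, with absolute differences), invisibly printed.
#' @export
reproduce_paper <- function(data_dir, config = NULL) {
  files <- file.path(data_dir, c("captures.csv", "plots.csv", "species.csv"))
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    stop("missing expected file(s): ", paste(basename(missing), collapse = ", "),
         " in ", data_dir)
  }
  if (is.null(config)) {
    config <- run_config(captures = files[1], plots = files[2],
                         registry = files[3])
  } else {
    config$captures <- files[1]
    config$plots <- files[2]
    config$registry <- files[3]
    config$scenario <- NULL
  }
  report <- run_pipeline(config)
  s <- report$summaries[[1]]
  est <- data.frame(period_label = s$compensation$means$level,
                    stringsAsFactors = FALSE)
  pull <- function(nm) {
    if (is.null(s[[nm]])) return(rep(NA_real_, nrow(est)))
    v <- s[[nm]]$means
    100 * v$estimate[match(est$period_label, v$level)]
  }
  est$compensation <- pull("compensation")
  est$total_ratio <- pull("total_ratio")
  est$prop_kr_control <- pull("prop_kr_control")
  cb_fit <- report$fits[[1]]$prop_cb
  est$prop_cb_exclosure <- if (is.null(cb_fit)) NA_real_ else {
    v <- marginal_means(cb_fit, "period_label", adjust = config$adjust,
                        at = list(treatment = "exclosure"))$means
    100 * v$estimate[match(est$period_label, v$level)]
  }
  ref <- paper_reference_estimates()
  out <- merge(est, ref, by = "period_label", suffixes = c("_est", "_ref"))
  for (nm in c("compensation", "total_ratio", "prop_kr_control",
               "prop_cb_exclosure")) {
    out[[paste0(nm, "_absdiff")]] <- abs(out[[paste0(nm, "_est")]] -
                                           out[[paste0(nm, "_ref")]])
  }
  print(out)
  invisible(out)
}
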