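#' Scenario configuration for the synthetic rodent community
#'
#' A scenario states the world the generator emulates: a balanced
#' control/exclosure design censused ~monthly over Feb 1988 - Jan 2020 with
#' occasional missed bouts; a kangaroo-rat-dominated control baseline that
#' erodes after the first time period; a colonizing pocket mouse absent
#' before mid-1996, dominant on exclosures in the middle period and scarce
#' afterwards; period-specific true compensation; lognormal individual body
#' masses; and temporally autocorrelated multiplicative plot-level noise.
#'
#' Per-period parameters (one value per period of `scheme`, defaults for the
#' standard three-period scheme):
#' \describe{
#'   \item{q}{kangaroo-rat share of control-plot total energy
#'     (0.92, 0.70, 0.70).}
#'   \item{comp}{true compensation: the fraction of the removed kangaroo-rat
#'     energy taken up by small granivores on exclosures (0.18, 0.58, 0.28).}
#'   \item{cb_excl}{colonizer share of *exclosure* total energy
#'     (0, 0.72, 0.26).}
#'   \item{cb_ctrl}{colonizer share of *control* total energy
#'     (0, 0.11, 0.005).}
#' }
#' The control small-granivore share is `sg_frac * (1 - q)` (default
#' `sg_frac = 0.75`), the remainder going to non-granivores.  `E0` is the
#' mean per-plot control total energy in metabolic units.  Noise is AR(1) on
#' the log scale, generated independently per plot and guild stream with
#' stationary sd `noise_sd` and monthly coefficient `noise_phi`.
#'
#' @param scheme a [period_scheme()].
#' @param n_plots_per_treatment plots per treatment (default 4).
#' @param plots optional [plot_table()]; default ids 1..n controls,
#'   n+1..2n exclosures.
#' @param q,comp,cb_excl,cb_ctrl per-period parameter vectors (see above).
#' @param sg_frac control small-granivore fraction of non-kangaroo-rat
#'   energy.
#' @param E0 mean per-plot control total energy (metabolic units).
#' @param noise_sd,noise_phi plot-level log-noise stationary sd and AR(1)
#'   coefficient.
#' @param mass_sd lognormal sd of individual body mass around species means.
#' @param miss_prob probability a monthly census bout is missed sitewide.
#' @param cb_event `c(year, month)` of the colonizer's arrival, or `"never"`.
#' @param cb_arrival_excl,cb_arrival_ctrl colonizer energy share between
#'   arrival and its first configured nonzero period.
#' @param quantization `"closest"` (accumulate individuals while each brings
#'   the plot's energy total closer to target) or `"poisson"` (Poisson
#'   individual count).
#' @param registry a [species_registry()]; the focal colonizer is
#'   `focal_species`.
#' @param focal_species colonizer species code (default `"PB"`).
#' @param seed integer RNG seed.
#' @return validated list of class `scenario_config`.
#' @export
scenario_config <- function(scheme = default_period_scheme(),
                            n_plots_per_treatment = 4,
                            plots = NULL,
                            q = c(0.92, 0.70, 0.70),
                            comp = c(0.18, 0.58, 0.28),
                            cb_excl = c(0, 0.72, 0.26),
                            cb_ctrl = c(0, 0.11, 0),
                            sg_frac = 0.75,
                            E0 = 2000,
                            noise_sd = 0.1,
                            noise_phi = 0.5,
                            mass_sd = 0.2,
                            miss_prob = 0.03,
                            cb_event = c(1996, 7),
                            cb_arrival_excl = 0.03,
                            cb_arrival_ctrl = 0.005,
                            quantization = c("closest", "poisson"),
                            registry = default_species_registry(),
                            focal_species = "PB",
                            seed = 1) {
  quantization <- match.arg(quantization)
  np <- nrow(scheme)
  for (nm in c("q", "comp", "cb_excl", "cb_ctrl")) {
    v <- get(nm)
    if (length(v) != np) stop(sprintf("'%s' needs one value per period", nm))
  }
  if (any(q < 0 | q > 1) || any(cb_excl < 0 | cb_excl > 1) ||
      any(cb_ctrl < 0 | cb_ctrl > 1)) {
    stop("shares must lie in [0, 1]")
  }
  if (noise_phi < 0 || noise_phi >= 1) stop("noise_phi must lie in [0, 1)")
  s <- sg_frac * (1 - q)
  if (any(q + s > 1 + 1e-12)) stop("control shares sum > 1")
  if (any(cb_ctrl > s + 1e-12)) {
    stop("colonizer control share exceeds the small-granivore share")
  }
  ratio <- 1 - q * (1 - comp)
  if (any(cb_excl * ratio > s + comp * q + 1e-12)) {
    stop("colonizer exclosure share exceeds the small-granivore share")
  }
  if (any(ratio < 0)) stop("compensation too negative: exclosure total < 0")
  if (is.null(plots)) {
    n <- n_plots_per_treatment
    plots <- plot_table(seq_len(2 * n),
                        rep(c("control", "exclosure"), each = n))
  }
  cfg <- list(schema_version = 1L, scheme = scheme, plots = plots,
              q = q, comp = comp, cb_excl = cb_excl, cb_ctrl = cb_ctrl,
              sg_frac = sg_frac, E0 = E0, noise_sd = noise_sd,
              noise_phi = noise_phi, mass_sd = mass_sd,
              miss_prob = miss_prob, cb_event = cb_event,
              cb_arrival_excl = cb_arrival_excl,
              cb_arrival_ctrl = cb_arrival_ctrl,
              quantization = quantization, registry = registry,
              focal_species = focal_species, seed = as.integer(seed))
  class(cfg) <- "scenario_config"
  cfg
}

#' Closed-form ground truth of a scenario
#'
#' Per period: true compensation `c_t`, true total energy ratio
#' `1 - q_t (1 - c_t)`, true kangaroo-rat control share `q_t`, and the
#' colonizer's configured shares.  All values follow algebraically from the
#' scenario parameters.
#'
#' @param config a [scenario_config()].
#' @return data.frame, one row per period.
#' @export
ground_truth <- function(config) {
  data.frame(
    period_label = config$scheme$label,
    compensation = config$comp,
    total_ratio = 1 - config$q * (1 - config$comp),
    prop_kr_control = config$q,
    prop_cb_exclosure = config$cb_excl,
    prop_cb_control = config$cb_ctrl,
    stringsAsFactors = FALSE
  )
}

#' Simulate capture records from a scenario
#'
#' For each censused month and plot, the generator draws guild energy
#' targets (period mean x exponentiated AR(1) log-noise), then converts each
#' target into individuals by sampling species (registry abundance weights)
#' and lognormal body masses, accumulating individuals while each brings the
#' accumulated metabolic total closer to the target.  Kangaroo-rat energy on
#' exclosures is identically zero; the colonizer appears only after its
#' event month.  Plot-months with no individuals at all are emitted as
#' trapped-but-empty sentinel rows so aggregation counts them as censused
#' zeros.  Deterministic under the config seed; the caller's RNG stream is
#' left untouched.
#'
#' @param config a [scenario_config()].
#' @return list with `records` (capture-record data.frame in the dialect
#'   [read_captures()] produces), `truth` ([ground_truth()]), and `config`.
#' @export
simulate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  with_local_seed(config$seed, simulate_scenario_impl(config))
}

simulate_scenario_impl <- function(config) {
  sch <- config$scheme
  all_mi <- seq(min(sch$start), max(sch$end))
  n_all <- length(all_mi)
  miss <- stats::runif(n_all) < config$miss_prob
  miss[c(1L, n_all)] <- FALSE  # keep the window endpoints censused
  kept <- which(!miss)
  per_idx_all <- as.integer(assign_period(all_mi, sch))

  plots <- config$plots
  n_plots <- nrow(plots)
  streams <- c("kr", "sgo", "cb", "oth")
  # AR(1) log-noise over the full month grid (gaps evolve through time)
  noise <- array(0, dim = c(n_all, n_plots, 4L))
  if (config$noise_sd > 0) {
    for (j in seq_len(n_plots)) for (s in 1:4) {
      z <- stats::rnorm(n_all, 0, config$noise_sd * sqrt(1 - config$noise_phi^2))
      e0 <- stats::rnorm(1, 0, config$noise_sd)
      noise[, j, s] <- as.numeric(stats::filter(z, config$noise_phi,
                                                method = "recursive",
                                                init = e0))
    }
  }

  event_mi <- if (identical(config$cb_event, "never") || is.null(config$cb_event)) {
    Inf
  } else month_index(config$cb_event[1], config$cb_event[2])

  reg <- config$registry
  pools <- list(
    kr = reg[reg$guild == "kangaroo_rat", ],
    sgo = reg[reg$guild == "small_granivore" & reg$species != config$focal_species, ],
    cb = reg[reg$species == config$focal_species, ],
    oth = reg[reg$guild == "other", ]
  )
  s_share <- config$sg_frac * (1 - config$q)
  ratio <- 1 - config$q * (1 - config$comp)
  # the small "arrival" share applies only between the colonizer's event
  # month and its first configured-positive period (the colonization era),
  # never to later periods where the configured share is a true zero
  first_pos <- function(x) if (any(x > 0)) min(which(x > 0)) else Inf
  arrival_ok_excl <- seq_len(nrow(sch)) < first_pos(config$cb_excl)
  arrival_ok_ctrl <- seq_len(nrow(sch)) < first_pos(config$cb_ctrl)

  acc <- vector("list", length(kept) * n_plots)
  ai <- 0L
  for (ii in seq_along(kept)) {
    im <- kept[ii]
    mi <- all_mi[im]
    k <- per_idx_all[im]
    ym <- c(mi %/% 12L, mi %% 12L + 1L)
    for (j in seq_len(n_plots)) {
      is_excl <- plots$treatment[j] == "exclosure"
      if (mi < event_mi) {
        cb_share <- 0
      } else if (is_excl) {
        cb_share <- if (config$cb_excl[k] > 0) config$cb_excl[k] * ratio[k]
                    else if (arrival_ok_excl[k]) config$cb_arrival_excl
                    else 0
      } else {
        cb_share <- if (config$cb_ctrl[k] > 0) config$cb_ctrl[k]
                    else if (arrival_ok_ctrl[k]) config$cb_arrival_ctrl
                    else 0
      }
      shares <- if (is_excl) {
        c(kr = 0, sgo = s_share[k] + config$comp[k] * config$q[k] - cb_share,
          cb = cb_share, oth = 1 - config$q[k] - s_share[k])
      } else {
        c(kr = config$q[k], sgo = s_share[k] - cb_share,
          cb = cb_share, oth = 1 - config$q[k] - s_share[k])
      }
      shares[shares < 0] <- 0
      targets <- config$E0 * shares * exp(noise[im, j, ])
      sp <- character(0)
      ms <- numeric(0)
      for (s in 1:4) {
        if (targets[s] <= 0) next
        ind <- draw_individuals(targets[s], pools[[streams[s]]],
                                config$mass_sd, config$quantization)
        sp <- c(sp, ind$species)
        ms <- c(ms, ind$mass)
      }
      ai <- ai + 1L
      acc[[ai]] <- if (length(sp)) {
        list(period = rep(ii, length(sp)), year = rep(ym[1], length(sp)),
             month = rep(ym[2], length(sp)), plot = rep(plots$plot[j], length(sp)),
             species = sp, mass_g = ms)
      } else {
        list(period = ii, year = ym[1], month = ym[2], plot = plots$plot[j],
             species = SENTINEL_NONE, mass_g = NA_real_)
      }
    }
  }
  rec <- data.frame(
    period = unlist(lapply(acc, `[[`, "period")),
    year = unlist(lapply(acc, `[[`, "year")),
    month = unlist(lapply(acc, `[[`, "month")),
    plot = unlist(lapply(acc, `[[`, "plot")),
    species = unlist(lapply(acc, `[[`, "species")),
    mass_g = unlist(lapply(acc, `[[`, "mass_g")),
    stringsAsFactors = FALSE
  )
  rec$mi <- month_index(rec$year, rec$month)
  rec$known <- TRUE
  list(records = rec, truth = ground_truth(config), config = config)
}

# Convert one guild energy target into individuals.
draw_individuals <- function(target, pool, mass_sd, quantization) {
  mm <- pool$mean_mass_g
  w <- pool$weight / sum(pool$weight)
  bbar <- sum(w * 5.69 * mm^0.75)
  if (quantization == "poisson") {
    n <- stats::rpois(1, target / bbar)
    if (n == 0) return(list(species = character(0), mass = numeric(0)))
    idx <- sample.int(length(mm), n, replace = TRUE, prob = w)
    mass <- draw_mass(mm[idx], mass_sd)
    return(list(species = pool$species[idx], mass = mass))
  }
  n_exp <- target / bbar
  N <- as.integer(ceiling(n_exp + 6 * sqrt(n_exp + 1) + 8))
  idx <- sample.int(length(mm), N, replace = TRUE, prob = w)
  mass <- draw_mass(mm[idx], mass_sd)
  b <- 5.69 * mass^0.75
  cum <- cumsum(b)
  while (cum[length(cum)] < target) {  # rarely: extend the draw
    idx2 <- sample.int(length(mm), N, replace = TRUE, prob = w)
    mass2 <- draw_mass(mm[idx2], mass_sd)
    idx <- c(idx, idx2)
    mass <- c(mass, mass2)
    b <- 5.69 * mass^0.75
    cum <- cumsum(b)
  }
  k <- findInterval(target, cum)  # individuals with cumulative total <= target
  below <- if (k == 0) 0 else cum[k]
  if (k < length(cum) && (cum[k + 1] - target) < (target - below)) k <- k + 1L
  if (k == 0) return(list(species = character(0), mass = numeric(0)))
  list(species = pool$species[idx[seq_len(k)]], mass = mass[seq_len(k)])
}

draw_mass <- function(mean_mass, mass_sd) {
  if (mass_sd <= 0) return(mean_mass)
  # meanlog offset keeps E[mass] equal to the species mean
  stats::rlnorm(length(mean_mass), log(mean_mass) - mass_sd^2 / 2, mass_sd)
}

#' Write / read a scenario file (versioned JSON schema)
#'
#' @param config a [scenario_config()]; @param path JSON file path.
#' @export
write_scenario <- function(config, path) {
  out <- unclass(config)
  out$scheme <- as.data.frame(out$scheme)
  out$plots <- as.data.frame(out$plots)
  out$registry <- as.data.frame(out$registry)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$schema_version) || raw$schema_version != 1L) {
    stop("unsupported scenario schema version")
  }
  scenario_config(
    scheme = period_scheme(raw$scheme$label, raw$scheme$start, raw$scheme$end),
    plots = plot_table(raw$plots$plot, raw$plots$treatment),
    q = raw$q, comp = raw$comp, cb_excl = raw$cb_excl, cb_ctrl = raw$cb_ctrl,
    sg_frac = raw$sg_frac, E0 = raw$E0, noise_sd = raw$noise_sd,
    noise_phi = raw$noise_phi, mass_sd = raw$mass_sd,
    miss_prob = raw$miss_prob,
    cb_event = if (identical(raw$cb_event, "never")) "never"
               else as.integer(raw$cb_event),
    cb_arrival_excl = raw$cb_arrival_excl,
    cb_arrival_ctrl = raw$cb_arrival_ctrl,
    quantization = raw$quantization,
    registry = species_registry(raw$registry$species, raw$registry$guild,
                                raw$registry$mean_mass_g, raw$registry$weight),
    focal_species = raw$focal_species,
    seed = raw$seed
  )
}
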