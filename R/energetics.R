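#' Individual metabolic rate from body mass
#'
#' Allometric scaling of basal metabolic rate with body mass,
#' `b = 5.69 * m^0.75`, with `m` in grams.  Units are left as the formula's
#' arbitrary metabolic units: every downstream statistic is a ratio or
#' proportion and therefore unit-free.
#'
#' @param mass_g positive body mass in grams (vectorized).
#' @return metabolic rate(s), same length as `mass_g`.
#' @examples
#' metabolic_rate(16)  # 5.69 * 8  = 45.52
#' metabolic_rate(81)  # 5.69 * 27 = 153.63
#' @export
metabolic_rate <- function(mass_g) {
  if (any(!is.finite(mass_g)) || any(mass_g <= 0)) {
    stop("mass_g must be positive and finite")
  }
  5.69 * mass_g^0.75
}

#' Aggregate capture records to treatment-level guild series
#'
#' For each census period and treatment, sums each individual's contribution
#' (metabolic rate for the energy columns, body mass for the biomass columns)
#' within each plot by guild, then averages the per-plot sums across the
#' treatment's censused plots.  A plot trapped in a period but yielding no
#' captures (sentinel `NONE` row) contributes a zero to that mean; a plot with
#' no row at all in a period is treated as not trapped and excluded from the
#' denominator.  Periods in which a treatment has no censused plot are omitted
#' and reported via a message.
#'
#' Unknown species (`known = FALSE`) are excluded from all sums.  The focal
#' colonizer (default `PB`, *C. baileyi*) additionally populates the `*_cb`
#' columns; it remains part of the small-granivore guild, so `cb <= sg`
#' always.
#'
#' @param records capture records (see [read_captures()]), filtered to the
#'   study window and selected plots, with no missing masses (see
#'   [impute_mass()]).
#' @param plots a [plot_table()]; records on plots outside it are dropped.
#' @param registry a [species_registry()].
#' @param focal_species species code for the colonizer columns.
#' @param etot_scope `"all"` (default): total energy/biomass includes every
#'   registered rodent, granivorous or not; `"granivores"`: totals restricted
#'   to kangaroo rats + small granivores.
#' @return data.frame of class `treatment_series`: one row per
#'   `(period, treatment)` with columns `period`, `year`, `month`, `mi`,
#'   `treatment`, `n_plots`, `energy_total`, `energy_kr`, `energy_sg`,
#'   `energy_cb`, `biomass_total`, `biomass_kr`, `biomass_sg`, `biomass_cb`.
#' @export
aggregate_treatments <- function(records, plots,
                                 registry = default_species_registry(),
                                 focal_species = "PB",
                                 etot_scope = c("all", "granivores")) {
  etot_scope <- match.arg(etot_scope)
  stopifnot(inherits(plots, "plot_table"))
  e <- guild_aggregate(records, plots, registry, focal_species, etot_scope,
                       transform = metabolic_rate)
  b <- guild_aggregate(records, plots, registry, focal_species, etot_scope,
                       transform = identity)
  stopifnot(identical(e[c("period", "treatment")], b[c("period", "treatment")]))
  out <- e
  guilds <- c("total", "kr", "sg", "cb", "other")
  names(out)[match(guilds, names(out))] <- paste0("energy_", guilds)
  for (g in guilds) out[[paste0("biomass_", g)]] <- b[[g]]
  class(out) <- c("treatment_series", "data.frame")
  attr(out, "etot_scope") <- etot_scope
  out
}

# Shared aggregation kernel, parameterized by the per-individual transform
# (metabolic_rate for energy, identity for biomass).  Exported for property
# testing of the energy/biomass equivalence.
#' @rdname aggregate_treatments
#' @param transform function mapping one individual's mass to its
#'   contribution.
#' @export
guild_aggregate <- function(records, plots,
                            registry = default_species_registry(),
                            focal_species = "PB",
                            etot_scope = c("all", "granivores"),
                            transform = metabolic_rate) {
  etot_scope <- match.arg(etot_scope)
  rec <- records[records$plot %in% plots$plot, , drop = FALSE]
  if (nrow(rec) == 0) stop("no records on the selected plots")
  rec$treatment <- plots$treatment[match(rec$plot, plots$plot)]

  # censused (period, treatment, plot) combinations: any row incl. sentinel
  dt <- data.table::as.data.table(rec)
  census <- unique(dt[, c("period", "year", "month", "mi", "treatment", "plot")])

  animals <- dt[dt$species != SENTINEL_NONE & dt$known, ]
  animals$guild <- registry$guild[match(animals$species, registry$species)]
  if (nrow(animals) && anyNA(animals$mass_g)) {
    stop("records contain missing masses; run impute_mass() first")
  }
  animals$value <- if (nrow(animals)) transform(animals$mass_g) else numeric(0)
  animals$is_cb <- animals$species == focal_species

  value <- guild <- is_cb <- kr <- sg <- cb <- other <- NULL  # R CMD check
  per_plot <- animals[, list(
    kr = sum(value[guild == "kangaroo_rat"]),
    sg = sum(value[guild == "small_granivore"]),
    other = sum(value[guild == "other"]),
    cb = sum(value[is_cb])
  ), by = c("period", "treatment", "plot")]

  # zero-capture censused plots enter with zeros
  full <- merge(census, per_plot, by = c("period", "treatment", "plot"),
                all.x = TRUE)
  for (cc in c("kr", "sg", "other", "cb")) {
    v <- full[[cc]]
    v[is.na(v)] <- 0
    data.table::set(full, j = cc, value = v)
  }
  agg <- full[, list(
    year = min(year), month = month[which.min(mi)], mi = min(mi),
    n_plots = .N,
    kr = sum(kr) / .N, sg = sum(sg) / .N,
    other = sum(other) / .N, cb = sum(cb) / .N
  ), by = c("period", "treatment")]
  agg$total <- if (etot_scope == "all") agg$kr + agg$sg + agg$other
               else agg$kr + agg$sg

  # report periods missing a treatment entirely
  n_tr <- table(agg$period)
  lonely <- names(n_tr)[n_tr < 2L]
  if (length(lonely)) {
    message(sprintf("aggregate: %d period(s) censused in one treatment only",
                    length(lonely)))
  }
  out <- as.data.frame(agg[order(agg$period, agg$treatment), ])
  out <- out[, c("period", "year", "month", "mi", "treatment", "n_plots",
                 "total", "kr", "sg", "cb", "other")]
  rownames(out) <- NULL
  out
}

#' Read/write a treatment series as tidy delimited text
#'
#' @param ts a `treatment_series` data.frame.
#' @param path CSV file path.
#' @export
write_treatment_series <- function(ts, path) {
  utils::write.csv(as.data.frame(ts), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_treatment_series
#' @export
read_treatment_series <- function(path) {
  out <- read_delim_auto(path)
  class(out) <- c("treatment_series", "data.frame")
  out
}
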