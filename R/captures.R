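#' Read monthly capture records
#'
#' Ingests a delimited capture table (comma default, tab accepted) into the
#' package's capture-record data.frame: one row per trapped individual with
#' columns `period` (census bout id), `year`, `month`, `plot`, `species`,
#' `mass_g`, plus `mi` (month index) and `known` (species present in the
#' registry or the `NONE` sentinel).
#'
#' Rows whose species code is absent from the registry are retained but
#' flagged `known = FALSE`; they are excluded from all guild sums downstream
#' and counted in the `diagnostics` attribute.  Rows with an unparseable date
#' or plot are dropped, collected in `diagnostics$bad_rows`, and reported via
#' a message.
#'
#' @param path delimited text file with header.
#' @param registry a [species_registry()].
#' @param col_map named character vector mapping the canonical names
#'   `period`, `year`, `month`, `plot`, `species`, `mass` to the file's
#'   column names.  Default matches the Portal data dialect
#'   (`wgt` for body mass).
#' @return data.frame of capture records with attribute `diagnostics`
#'   (list: `n_unknown_species`, `unknown_codes`, `bad_rows`).
#' @export
read_captures <- function(path, registry = default_species_registry(),
                          col_map = c(period = "period", year = "year",
                                      month = "month", plot = "plot",
                                      species = "species", mass = "wgt")) {
  tab <- read_delim_auto(path)
  need <- c("period", "year", "month", "plot", "species")
  for (k in need) {
    if (!col_map[[k]] %in% names(tab)) {
      stop(sprintf("capture table missing required column '%s'", col_map[[k]]))
    }
  }
  mass_col <- col_map[["mass"]]
  mass <- if (mass_col %in% names(tab)) {
    suppressWarnings(as.numeric(tab[[mass_col]]))
  } else {
    rep(NA_real_, nrow(tab))
  }
  rec <- data.frame(
    period = suppressWarnings(as.integer(tab[[col_map[["period"]]]])),
    year = suppressWarnings(as.integer(tab[[col_map[["year"]]]])),
    month = suppressWarnings(as.integer(tab[[col_map[["month"]]]])),
    plot = suppressWarnings(as.integer(tab[[col_map[["plot"]]]])),
    species = as.character(tab[[col_map[["species"]]]]),
    mass_g = mass,
    stringsAsFactors = FALSE
  )
  bad <- is.na(rec$period) | is.na(rec$year) | is.na(rec$month) |
    is.na(rec$plot) | rec$month < 1 | rec$month > 12
  bad_rows <- which(bad)
  if (length(bad_rows)) {
    message(sprintf("read_captures: dropped %d malformed row(s)", length(bad_rows)))
    rec <- rec[!bad, , drop = FALSE]
  }
  rec$mass_g[!is.na(rec$mass_g) & rec$mass_g <= 0] <- NA_real_
  rec$mi <- month_index(rec$year, rec$month)
  rec$known <- rec$species %in% c(registry$species, SENTINEL_NONE)
  unknown <- unique(rec$species[!rec$known])
  if (length(unknown)) {
    message(sprintf("read_captures: %d record(s) with species outside registry: %s",
                    sum(!rec$known), paste(unknown, collapse = ", ")))
  }
  rownames(rec) <- NULL
  attr(rec, "diagnostics") <- list(
    n_unknown_species = sum(!rec$known),
    unknown_codes = unknown,
    bad_rows = bad_rows
  )
  rec
}

#' Write capture records back to delimited text
#'
#' Inverse of [read_captures()]: writes the canonical columns under the
#' default Portal-dialect header so that a read/write round trip preserves
#' record count and field values.
#'
#' @param records capture-record data.frame.
#' @param path output file path (CSV).
#' @export
write_captures <- function(records, path) {
  out <- records[, c("period", "year", "month", "plot", "species", "mass_g")]
  names(out)[names(out) == "mass_g"] <- "wgt"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Restrict records to a study window
#'
#' Keeps records whose census month lies in `[start, end]` (month indices,
#' inclusive); input ordering is preserved.
#'
#' @param records capture-record data.frame with an `mi` column.
#' @param start,end integer month indices; default the Feb 1988 - Jan 2020
#'   study window.
#' @export
filter_window <- function(records,
                          start = default_study_window()$start,
                          end = default_study_window()$end) {
  if (start > end) stop("window start after end")
  records[records$mi >= start & records$mi <= end, , drop = FALSE]
}

#' Impute missing body masses
#'
#' Replaces missing masses with the species' mean mass computed from the
#' non-missing masses in `records`, falling back to the registry mean for
#' species with no measured mass at all.  The imputation count is reported via
#' a message and returned as attribute `n_imputed`.
#'
#' @inheritParams filter_window
#' @param registry a [species_registry()].
#' @export
impute_mass <- function(records, registry = default_species_registry()) {
  is_animal <- records$species != SENTINEL_NONE
  need <- is_animal & is.na(records$mass_g)
  if (any(need)) {
    obs_mean <- tapply(records$mass_g[is_animal], records$species[is_animal],
                       mean, na.rm = TRUE)
    fill <- obs_mean[records$species[need]]
    reg_mean <- registry$mean_mass_g[match(records$species[need], registry$species)]
    fill[!is.finite(fill)] <- reg_mean[!is.finite(fill)]
    records$mass_g[need] <- as.numeric(fill)
    message(sprintf("impute_mass: imputed %d missing mass(es)", sum(need)))
  }
  still <- is_animal & is.na(records$mass_g)
  if (any(still)) {
    stop("no mass available (measured or registry) for species: ",
         paste(unique(records$species[still]), collapse = ", "))
  }
  attr(records, "n_imputed") <- sum(need)
  records
}

#' Detect the establishment census of a colonizing species
#'
#' Establishment is defined as the first census period in which the species
#' was captured on every exclosure plot.
#'
#' @inheritParams filter_window
#' @param species_code the colonizer's species code (e.g. `"PB"`).
#' @param exclosure_plots integer vector of exclosure plot ids.
#' @return the smallest qualifying `period` id, or `NA_integer_` ("never") if
#'   no census period has the species on all exclosure plots.
#' @export
detect_establishment <- function(records, species_code, exclosure_plots) {
  exclosure_plots <- unique(as.integer(exclosure_plots))
  if (length(exclosure_plots) == 0) stop("empty exclosure plot set")
  hit <- records[records$species == species_code &
                   records$plot %in% exclosure_plots, c("period", "plot")]
  if (nrow(hit) == 0) return(NA_integer_)
  n_by_period <- tapply(hit$plot, hit$period, function(p) length(unique(p)))
  full <- as.integer(names(n_by_period)[n_by_period == length(exclosure_plots)])
  if (length(full) == 0) NA_integer_ else min(full)
}
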