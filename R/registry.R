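#' Species registry
#'
#' Maps species codes to a functional guild and a mean body mass.  Guilds are
#' disjoint:
#' \describe{
#'   \item{kangaroo_rat}{the removed dominant guild: *Dipodomys spectabilis*
#'     (DS), *D. merriami* (DM), *D. ordii* (DO).}
#'   \item{small_granivore}{the 12 granivorous rodent species other than
#'     kangaroo rats, including the focal colonizer *Chaetodipus baileyi*
#'     (PB).}
#'   \item{other}{non-granivorous rodents (grasshopper mice, cotton rats,
#'     woodrats); included in total energy use under the default all-rodent
#'     scope.}
#' }
#' `mean_mass_g` is used to impute missing body masses and to parameterize the
#' synthetic generator; `weight` is a relative-abundance weight used only by
#' the generator when drawing individuals within a guild.
#'
#' The special code `NONE` is not a species: it marks a plot that was trapped
#' in a census but yielded no captures, so the plot still counts in
#' treatment-level means.
#'
#' @param species,guild,mean_mass_g,weight parallel vectors defining the
#'   registry.
#' @return data.frame of class `species_registry`.
#' @export
species_registry <- function(species, guild, mean_mass_g,
                             weight = rep(1, length(species))) {
  guild <- as.character(guild)
  ok <- guild %in% c("kangaroo_rat", "small_granivore", "other")
  if (any(!ok)) stop("unknown guild: ", paste(unique(guild[!ok]), collapse = ", "))
  if (any(mean_mass_g <= 0)) stop("mean_mass_g must be positive")
  if (anyDuplicated(species)) stop("duplicate species codes in registry")
  reg <- data.frame(species = as.character(species), guild = guild,
                    mean_mass_g = as.numeric(mean_mass_g),
                    weight = as.numeric(weight), stringsAsFactors = FALSE)
  class(reg) <- c("species_registry", "data.frame")
  reg
}

#' @rdname species_registry
#' @details `default_species_registry()` returns the registry for the Portal
#'   rodent community with field-typical mean masses (grams).
#' @export
default_species_registry <- function() {
  species_registry(
    species = c("DS", "DM", "DO",
                "BA", "PB", "PH", "PI", "PP", "PF",
                "PE", "PL", "PM", "RF", "RM", "RO",
                "OT", "OL", "SH", "NTA"),
    guild = c(rep("kangaroo_rat", 3), rep("small_granivore", 12),
              rep("other", 4)),
    mean_mass_g = c(120, 43, 48,
                    8, 30, 31, 15, 16, 7,
                    21, 20, 21, 13, 10, 9,
                    24, 32, 70, 160),
    weight = c(0.10, 0.65, 0.25,
               0.03, 1.00, 0.02, 0.05, 0.30, 0.15,
               0.10, 0.05, 0.10, 0.03, 0.15, 0.02,
               0.50, 0.20, 0.20, 0.10)
  )
}

#' Sentinel species code marking a trapped-but-empty plot census
#' @export
SENTINEL_NONE <- "NONE"

#' Plot-treatment tables
#'
#' A plot table maps plot ids to experimental treatments: `control` (all
#' rodents admitted) or `exclosure` (fence gates exclude kangaroo rats).
#'
#' @param plot integer plot ids.
#' @param treatment character vector, each `"control"` or `"exclosure"`.
#' @return data.frame of class `plot_table`.
#' @export
plot_table <- function(plot, treatment) {
  treatment <- as.character(treatment)
  if (any(!treatment %in% c("control", "exclosure"))) {
    stop("treatment must be 'control' or 'exclosure'")
  }
  if (anyDuplicated(plot)) stop("duplicate plot ids")
  pt <- data.frame(plot = as.integer(plot), treatment = treatment,
                   stringsAsFactors = FALSE)
  class(pt) <- c("plot_table", "data.frame")
  pt
}

#' @rdname plot_table
#' @details `default_plot_candidates()` is the candidate set of long-term
#'   unchanged plots: four controls and five exclosures, from which a balanced
#'   four-per-treatment design is drawn with [select_plots()].
#' @export
default_plot_candidates <- function() {
  plot_table(plot = c(4, 11, 14, 17, 3, 8, 15, 19, 21),
             treatment = c(rep("control", 4), rep("exclosure", 5)))
}

#' Select a balanced plot design
#'
#' Takes all plots of a treatment when exactly `n_per_treatment` are
#' available, and draws a uniform random subset (without replacement, seeded)
#' when more are available.  An explicit `override` list of plot ids bypasses
#' random selection entirely.
#'
#' @param candidates a [plot_table()] of candidate plots.
#' @param n_per_treatment plots to retain per treatment (default 4).
#' @param seed integer seed for the one stochastic design step; default 1988.
#'   Echoed as attribute `seed` on the result.
#' @param override optional integer vector of plot ids to use verbatim.
#' @return a [plot_table()] with exactly `n_per_treatment` plots per
#'   treatment, ordered by treatment then plot id.
#' @export
select_plots <- function(candidates, n_per_treatment = 4, seed = 1988,
                         override = NULL) {
  stopifnot(inherits(candidates, "plot_table"))
  if (!is.null(override)) {
    keep <- candidates[candidates$plot %in% as.integer(override), ]
    sel <- plot_table(keep$plot, keep$treatment)
  } else {
    pieces <- lapply(c("control", "exclosure"), function(tr) {
      avail <- candidates[candidates$treatment == tr, ]
      if (nrow(avail) < n_per_treatment) {
        stop(sprintf("only %d %s plots available, %d requested",
                     nrow(avail), tr, n_per_treatment))
      }
      if (nrow(avail) == n_per_treatment) return(avail)
      picked <- with_local_seed(seed + match(tr, c("control", "exclosure")), {
        sample(avail$plot, n_per_treatment)
      })
      avail[avail$plot %in% picked, ]
    })
    both <- do.call(rbind, pieces)
    sel <- plot_table(both$plot, both$treatment)
  }
  sel <- sel[order(sel$treatment, sel$plot), ]
  rownames(sel) <- NULL
  class(sel) <- c("plot_table", "data.frame")
  counts <- table(factor(sel$treatment, c("control", "exclosure")))
  if (is.null(override) && any(counts != n_per_treatment)) {
    stop("selection failed to balance treatments")  # defensive; not reachable
  }
  attr(sel, "seed") <- if (is.null(override)) seed else NA_integer_
  sel
}

#' Read registry / plot tables from delimited text
#'
#' @param path path to a comma- or tab-delimited file with header.  Registry
#'   columns: `species`, `guild`, `mean_mass_g`, optional `weight`.  Plot
#'   table columns: `plot`, `treatment`.
#' @return see [species_registry()] / [plot_table()].
#' @export
read_species_registry <- function(path) {
  tab <- read_delim_auto(path)
  need <- c("species", "guild", "mean_mass_g")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("registry file missing column(s): ",
                         paste(miss, collapse = ", "))
  w <- if ("weight" %in% names(tab)) tab$weight else rep(1, nrow(tab))
  species_registry(tab$species, tab$guild, tab$mean_mass_g, w)
}

#' @rdname read_species_registry
#' @export
read_plot_table <- function(path) {
  tab <- read_delim_auto(path)
  miss <- setdiff(c("plot", "treatment"), names(tab))
  if (length(miss)) stop("plot file missing column(s): ",
                         paste(miss, collapse = ", "))
  plot_table(tab$plot, tab$treatment)
}

# comma-or-tab delimited reader used by all table ingestion
read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    strip.white = TRUE, na.strings = c("NA", ""))
}

# run code under a temporary RNG state, restoring the caller's stream
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}
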