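#' Define a synthetic monitoring scenario for one site
#'
#' A scenario fixes the ground truth a synthetic site is generated from:
#' true pre- and post-restoration mean salinities, observation noise,
#' per-depth offsets, an optional seasonal cycle, the monitoring span and a
#' lag phase (initial post-restoration years whose annual mean is forced
#' below threshold). Identical scenario + seed always yield the identical
#' dataset.
#'
#' @param site_id Site identifier.
#' @param true_pre_mean,true_post_mean True mean salinities (psu) around
#'   which observations are drawn.
#' @param observation_sd Independent observation noise SD (psu), >= 0.
#' @param depth_offsets Named numeric, psu shifts per depth class; default
#'   all zero. Names must be among `shallow`, `medium`, `deep`.
#' @param seasonal_amplitude Amplitude (psu) of a yearly sinusoid; default 0
#'   so basic scenarios are season-free.
#' @param monitoring_start,monitoring_end Monitoring years (calendar).
#' @param restoration_date Restoration date within the monitoring span.
#' @param lag_years Count of initial post-restoration years pulled below
#'   the 18 psu threshold; requires `true_post_mean` > 18 (a lag phase is
#'   meaningless for a site that never surpasses it).
#' @param lag_mean Salinity mean used in lag years; default 2 psu below
#'   threshold.
#' @param area_m2 Marsh area carried into the generated site record.
#' @param n_per_year Observations per transect, depth class and year, >= 1.
#' @param transects Number of transects, >= 1.
#' @return Object of class `site_scenario`.
#' @export
site_scenario <- function(site_id = "synthetic",
                          true_pre_mean, true_post_mean,
                          observation_sd = 2,
                          depth_offsets = c(shallow = 0, medium = 0, deep = 0),
                          seasonal_amplitude = 0,
                          monitoring_start = 1998, monitoring_end = 2015,
                          restoration_date = "2003-11-01",
                          lag_years = 0L,
                          lag_mean = salinity_threshold_psu - 2,
                          area_m2 = 10000,
                          n_per_year = 4L, transects = 3L) {
  restoration_date <- as.Date(restoration_date)
  restoration_year <- as.integer(format(restoration_date, "%Y"))
  stopifnot(observation_sd >= 0, n_per_year >= 1, transects >= 1, area_m2 > 0)
  if (restoration_year < monitoring_start || restoration_year > monitoring_end) {
    stop("restoration date must fall inside the monitoring span", call. = FALSE)
  }
  if (length(setdiff(names(depth_offsets), names(depth_classes)))) {
    stop("depth_offsets names must be among: ",
         paste(names(depth_classes), collapse = ", "), call. = FALSE)
  }
  offsets <- c(shallow = 0, medium = 0, deep = 0)
  offsets[names(depth_offsets)] <- depth_offsets
  post_span <- monitoring_end - restoration_year + 1
  if (lag_years > 0 && true_post_mean <= salinity_threshold_psu) {
    stop("inconsistent scenario: lag_years > 0 but true_post_mean never ",
         "surpasses the threshold", call. = FALSE)
  }
  if (lag_years > post_span) {
    stop("lag_years exceeds the post-restoration monitoring span (", post_span,
         " years)", call. = FALSE)
  }
  structure(
    list(site_id = site_id,
         true_pre_mean = true_pre_mean, true_post_mean = true_post_mean,
         observation_sd = observation_sd, depth_offsets = offsets,
         seasonal_amplitude = seasonal_amplitude,
         monitoring_start = monitoring_start, monitoring_end = monitoring_end,
         restoration_date = restoration_date, restoration_year = restoration_year,
         lag_years = as.integer(lag_years), lag_mean = lag_mean,
         area_m2 = area_m2,
         n_per_year = as.integer(n_per_year), transects = as.integer(transects)),
    class = "site_scenario"
  )
}

scenario_truth <- function(scenario, threshold = salinity_threshold_psu) {
  outcome <- classify_site(scenario$true_pre_mean, scenario$true_post_mean, threshold)
  post_span <- scenario$monitoring_end - scenario$restoration_year + 1
  qualifying <- if (scenario$true_post_mean > threshold) {
    post_span - scenario$lag_years
  } else {
    0L
  }
  list(intended_outcome = outcome,
       intended_qualifying_years = as.integer(qualifying),
       scenario = scenario)
}

#' Generate a synthetic salinity monitoring dataset
#'
#' Draws observations as true mean + depth offset + seasonal sinusoid +
#' independent normal noise, truncated at 0 psu. Each monitoring year gets
#' `n_per_year` sampling dates per transect and depth class, spread through
#' the year. In lag years the generating mean is replaced by `lag_mean`
#' (below threshold). The draw is fully determined by `(scenario, seed)`.
#'
#' @param scenario A [site_scenario()].
#' @param seed Integer seed; required for reproducibility.
#' @return List with `observations` (tibble in the ingest schema), `site`
#'   (one-row site-record tibble: `site_id`, `area_m2`, `area_ha`,
#'   `restoration_date`, `monitoring_start`, `monitoring_end`) and `truth`
#'   (`intended_outcome`, `intended_qualifying_years`, `scenario`).
#' @export
generate_site <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "site_scenario"))
  truth <- scenario_truth(scenario)
  years <- seq(scenario$monitoring_start, scenario$monitoring_end)
  lag_set <- if (scenario$lag_years > 0) {
    seq(scenario$restoration_year, length.out = scenario$lag_years)
  } else {
    integer(0)
  }
  grid <- expand.grid(
    year = years,
    transect = seq_len(scenario$transects),
    depth_class = names(depth_classes),
    k = seq_len(scenario$n_per_year),
    stringsAsFactors = FALSE
  )
  # sampling dates spread through each year, deterministic given the grid
  frac <- (grid$k - 0.5) / scenario$n_per_year
  doy <- pmax(1, pmin(365, round(frac * 365)))
  dates <- as.Date(paste0(grid$year, "-01-01")) + (doy - 1)
  is_post <- dates >= scenario$restoration_date
  base <- ifelse(is_post, scenario$true_post_mean, scenario$true_pre_mean)
  base[is_post & grid$year %in% lag_set] <- scenario$lag_mean
  mu <- base +
    scenario$depth_offsets[grid$depth_class] +
    scenario$seasonal_amplitude * sin(2 * pi * frac)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sal <- pmax(0, mu + rnorm(nrow(grid), sd = scenario$observation_sd))
  obs <- tibble::tibble(
    site_id = scenario$site_id,
    date = dates,
    transect_id = paste0("T", grid$transect),
    depth_class = grid$depth_class,
    salinity_psu = as.numeric(sal)
  )
  obs <- obs[order(obs$date, obs$transect_id, obs$depth_class), ]
  site <- tibble::tibble(
    site_id = scenario$site_id,
    area_m2 = scenario$area_m2,
    area_ha = scenario$area_m2 / 1e4,
    restoration_date = scenario$restoration_date,
    monitoring_start = scenario$monitoring_start,
    monitoring_end = scenario$monitoring_end
  )
  list(observations = obs, site = site, truth = truth)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Monitored restoration sites: packaged six-site metadata table
#'
#' The six Massachusetts restoration projects with pre- and post-restoration
#' salinity monitoring: name, location, monitoring window, restoration
#' date, post-restoration monitoring years, observation counts, pooled
#' pre/post salinity means with standard errors, and marsh area.
#'
#' @return Tibble with one row per site; `area_ha` is derived as
#'   `area_m2 / 10000`, and `restoration_year` from the restoration date.
#' @export
table1_sites <- function() {
  path <- system.file("extdata", "table1_sites.csv", package = "marshmethane",
                      mustWork = TRUE)
  sites <- readr::read_csv(path, col_types = readr::cols(
    site_id = readr::col_character(),
    name = readr::col_character(),
    location = readr::col_character(),
    monitoring_start = readr::col_integer(),
    monitoring_end = readr::col_integer(),
    restoration_date = readr::col_date(),
    post_restoration_years = readr::col_integer(),
    n_obs = readr::col_integer(),
    pre_mean_psu = readr::col_double(),
    pre_se_psu = readr::col_double(),
    post_mean_psu = readr::col_double(),
    post_se_psu = readr::col_double(),
    area_m2 = readr::col_double()
  ), progress = FALSE)
  sites$area_ha <- sites$area_m2 / 1e4
  sites$restoration_year <- as.integer(format(sites$restoration_date, "%Y"))
  sites
}

#' Generate a synthetic regional marsh inventory
#'
#' Draws per-marsh areas from a lognormal distribution and
#' restriction-effect scores from a beta distribution, reproducibly under a
#' seed. The returned tibble carries the generator's own filtered totals at
#' the stated threshold as attributes `truth_filtered_n` and
#' `truth_filtered_ha`, so downstream filtering can be checked exactly.
#'
#' @param n_marshes Number of marshes, >= 0.
#' @param area_meanlog,area_sdlog Lognormal parameters for area (ha);
#'   defaults give a median of ~2 ha with a long right tail, matching the
#'   skew of real marsh-size distributions.
#' @param effect_shape1,effect_shape2 Beta parameters for the effect score.
#' @param effect_threshold Threshold used for the ground-truth filtered
#'   totals, default 0.5.
#' @param seed Integer seed.
#' @return Tibble `marsh_id`, `area_ha`, `effect_score` with truth
#'   attributes.
#' @export
generate_inventory <- function(n_marshes,
                               area_meanlog = log(2), area_sdlog = 1,
                               effect_shape1 = 2, effect_shape2 = 2,
                               effect_threshold = 0.5,
                               seed = 1L) {
  stopifnot(n_marshes >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  inv <- tibble::tibble(
    marsh_id = sprintf("marsh_%04d", seq_len(n_marshes)),
    area_ha = rlnorm(n_marshes, area_meanlog, area_sdlog),
    effect_score = rbeta(n_marshes, effect_shape1, effect_shape2)
  )
  keep <- inv$effect_score > effect_threshold
  attr(inv, "truth_filtered_n") <- sum(keep)
  attr(inv, "truth_filtered_ha") <- sum(inv$area_ha[keep])
  attr(inv, "effect_threshold") <- effect_threshold
  inv
}
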