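#' IPCC global warming potential table
#'
#' Global warming potentials (GWP) for CO2, non-fossil CH4 and N2O across
#' IPCC assessment reports AR4, AR5 and AR6, at the 100-year and 20-year
#' horizons, as used in blue-carbon crediting. AR5 reports ranges (without
#' vs with climate-carbon feedback), stored as `value` (lower) and
#' `value_high`; AR6 reports symmetric uncertainties, stored in
#' `uncertainty`. The crediting default is the AR6 100-year CH4 value of
#' 27.2.
#'
#' @return Tibble with columns `gas`, `lifetime_yr`, `report`, `horizon_yr`,
#'   `value`, `value_high`, `uncertainty`.
#' @export
gwp_table <- function() {
  path <- system.file("extdata", "gwp_ipcc.csv", package = "marshmethane",
                      mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    gas = readr::col_character(),
    lifetime_yr = readr::col_double(),
    report = readr::col_character(),
    horizon_yr = readr::col_integer(),
    value = readr::col_double(),
    value_high = readr::col_double(),
    uncertainty = readr::col_double()
  ), progress = FALSE)
}

#' Look up one GWP entry
#'
#' @param gas `"CO2"`, `"CH4_nonfossil"` or `"N2O"`.
#' @param report Assessment report: `"AR4"`, `"AR5"` or `"AR6"`.
#' @param horizon Time horizon in years: 100 or 20.
#' @return One-row tibble from [gwp_table()].
#' @export
gwp_entry <- function(gas = "CH4_nonfossil", report = "AR6", horizon = 100) {
  tab <- gwp_table()
  row <- tab[tab$gas == gas & tab$report == report & tab$horizon_yr == horizon, ]
  if (nrow(row) != 1) {
    stop("no GWP entry for gas=", gas, ", report=", report, ", horizon=", horizon,
         call. = FALSE)
  }
  row
}

gwp_numeric <- function(gwp, expect_gas = "CH4_nonfossil") {
  if (is.data.frame(gwp)) {
    if (nrow(gwp) != 1) stop("gwp must be a single entry", call. = FALSE)
    if (!identical(gwp$gas, expect_gas)) {
      stop("GWP entry is for ", gwp$gas, ", not ", expect_gas,
           "; pass the methane entry", call. = FALSE)
    }
    gwp$value
  } else if (is.numeric(gwp) && length(gwp) == 1 && is.finite(gwp) && gwp > 0) {
    gwp
  } else {
    stop("gwp must be a positive number or a one-row gwp_table() entry", call. = FALSE)
  }
}

#' Annual Verified Carbon Units from avoided methane
#'
#' Converts annual avoided methane (metric tons CH4/yr) to CO2-equivalent
#' credits: `avoided_t * GWP_CH4 + (c0 - c1)`, where one Verified Carbon
#' Unit (VCU) equals one metric ton of CO2e avoided. The optional `c0`/`c1`
#' terms accept additional pre/post CO2e flows (soil carbon, N2O, ...)
#' already expressed in metric tons CO2e per year; they default to zero.
#'
#' @param avoided_t Avoided methane, metric tons CH4 per year.
#' @param gwp Methane GWP: a positive number (default 27.2, the AR6 100-yr
#'   non-fossil CH4 value) or a one-row [gwp_table()] entry for
#'   `CH4_nonfossil`. Passing a CO2 or N2O entry is a configuration error.
#' @param c0,c1 Additional CO2e terms pre/post restoration, t CO2e/yr.
#' @return VCUs per year (unrounded).
#' @export
vcu_annual <- function(avoided_t, gwp = 27.2, c0 = 0, c1 = 0) {
  g <- gwp_numeric(gwp)
  if (any(!is.finite(c(c0, c1)))) stop("additional CO2e terms must be finite", call. = FALSE)
  avoided_t * g + (c0 - c1)
}

#' Accumulate VCUs over each site's qualifying years
#'
#' Sums unrounded per-site annual VCUs times each site's qualifying-year
#' count. No rounding happens inside the accumulation; registry-style
#' whole-credit rendering is applied only at reporting time.
#'
#' @param vcus_per_year Numeric vector of per-site annual VCUs (unrounded).
#' @param years Matching vector of qualifying-year counts, >= 0.
#' @return Total VCUs (unrounded).
#' @export
cumulative_vcus <- function(vcus_per_year, years) {
  if (length(vcus_per_year) != length(years)) {
    stop("vcus_per_year and years must have the same length", call. = FALSE)
  }
  if (length(years) && any(years < 0)) stop("years must be non-negative", call. = FALSE)
  sum(vcus_per_year * years)
}

#' Price credits at a market rate
#'
#' @param vcus Credit count (VCU = metric tons CO2e).
#' @param price Market price in dollars per metric ton CO2e; default $20.
#' @return Revenue in dollars; VCU monetary values are not discounted.
#' @export
credit_revenue <- function(vcus, price = 20) {
  if (price < 0) stop("price must be non-negative", call. = FALSE)
  vcus * price
}

#' Credits and revenue over a fixed crediting window
#'
#' Projects a combined annual VCU rate over an inclusive year window and
#' prices it. Credits are accumulated unrounded, then rendered as whole
#' credits (registries issue integral units) before pricing, so the revenue
#' equals whole credits times the price.
#'
#' @param vcus_per_year_total Combined annual VCU rate (unrounded).
#' @param start_year,end_year Inclusive window, `end_year >= start_year`.
#' @param price Dollars per metric ton CO2e, default 20.
#' @return List with `credits` (unrounded), `credits_whole` and `revenue`.
#' @export
crediting_window <- function(vcus_per_year_total, start_year, end_year, price = 20) {
  if (end_year < start_year) stop("end_year must be >= start_year", call. = FALSE)
  credits <- vcus_per_year_total * (end_year - start_year + 1)
  whole <- round(credits)
  list(credits = credits, credits_whole = whole,
       revenue = credit_revenue(whole, price))
}

#' Render the annual avoided-emissions / VCU summary table
#'
#' Reproduces the published summary convention for a two-factor comparison:
#' per-site annual avoided emissions rounded to 2 decimal places, annual
#' VCUs computed from those *displayed* (2 d.p.) emissions times the GWP and
#' rounded to 1 decimal place, and a totals column formed by summing the
#' rounded site columns. This display convention is deliberately separate
#' from the computational path: accumulation functions
#' ([cumulative_vcus()], [crediting_window()]) always use unrounded values.
#'
#' @param abatement Tibble from [avoided_emissions()] (one scenario).
#' @param gwp Methane GWP (default 27.2).
#' @param sites_keep Optional character vector of site_ids to include
#'   (defaults to sites with positive abatement).
#' @return Tibble with one row per site plus a `Total` row: `site_id`,
#'   `annual_t_2dp`, `gwp`, `vcus_per_year_1dp`.
#' @export
table3_report <- function(abatement, gwp = 27.2, sites_keep = NULL) {
  g <- gwp_numeric(gwp)
  if (is.null(sites_keep)) sites_keep <- abatement$site_id[abatement$annual_t > 0]
  sub <- abatement[abatement$site_id %in% sites_keep, , drop = FALSE]
  e2 <- round(sub$annual_t, 2)
  vcu1 <- round(e2 * g, 1)
  tibble::tibble(
    site_id = c(sub$site_id, "Total"),
    annual_t_2dp = c(e2, sum(e2)),
    gwp = g,
    vcus_per_year_1dp = c(vcu1, sum(vcu1))
  )
}
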