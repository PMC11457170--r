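#' Full methane-abatement valuation for a set of monitored sites
#'
#' Runs the complete accounting chain on a site metadata table: classify
#' each site against the salinity threshold, compute avoided emissions
#' under each pre-restoration emission-factor scenario, credit them as
#' VCUs, price them at the market rate, value them against the
#' social-cost-of-methane schedule, and scale the per-hectare rate to a
#' regional inventory.
#'
#' Successful sites are those whose pre mean is strictly below and post
#' mean strictly above the threshold; all other sites contribute zero.
#' Every intermediate is carried at full precision; printed-convention
#' rounding lives in [table3_report()] / [table4_report()].
#'
#' @param sites Site table in the [table1_sites()] schema (needs `site_id`,
#'   `area_m2`, `pre_mean_psu`, `post_mean_psu`, `post_restoration_years`).
#'   Qualifying-year counts default to the recorded
#'   `post_restoration_years`; recompute with [qualifying_years()] when raw
#'   observations are available.
#' @param ef_pre_values Named numeric vector of pre-restoration emission
#'   factors (gC m^-2 yr^-1) for impaired marsh; default the geometric-mean
#'   and true-mean scenarios.
#' @param ef_post Post-restoration emission factor; default the published
#'   0.46 gC m^-2 yr^-1.
#' @param gwp Methane GWP; default 27.2 (AR6, 100-yr).
#' @param price Credit price, $ per t CO2e; default 20.
#' @param schedule `scm_schedule` for social valuation; default packaged 3%.
#' @param start,end Valuation/crediting window; defaults 2021--2050.
#' @param inventory Optional [marsh_inventory()] for statewide scaling;
#'   default [ma_inventory()]. Use `NULL` to skip scaling.
#' @param threshold Salinity threshold, psu; default 18.
#' @return List with elements `sites` (classified site table), `abatement`
#'   (per site x scenario tibble), `summary` (per-scenario tibble: per-ha
#'   rate, cumulative t, cumulative VCUs, revenue, window credits/revenue,
#'   cumulative social benefit), `statewide` (per-scenario tibble, or NULL),
#'   plus the `schedule`, `gwp` and `price` used.
#' @export
restoration_valuation <- function(sites = table1_sites(),
                                  ef_pre_values = c(geometric_mean = 19.4,
                                                    true_mean = 41.6),
                                  ef_post = 0.46,
                                  gwp = 27.2, price = 20,
                                  schedule = scm_schedule(3),
                                  start = 2021, end = 2050,
                                  inventory = ma_inventory(),
                                  threshold = salinity_threshold_psu) {
  if (is.null(names(ef_pre_values))) {
    names(ef_pre_values) <- paste0("EF_", format(ef_pre_values))
  }
  sites$outcome <- classify_site(sites$pre_mean_psu, sites$post_mean_psu, threshold)
  if (!"qualifying_years" %in% names(sites)) {
    sites$qualifying_years <- sites$post_restoration_years
  }
  g <- gwp_numeric(gwp)

  abatement <- dplyr::bind_rows(lapply(names(ef_pre_values), function(lbl) {
    avoided_emissions(sites, ef_pre_values[[lbl]], ef_post, label = lbl)
  }))

  summary <- dplyr::bind_rows(lapply(names(ef_pre_values), function(lbl) {
    ab <- abatement[abatement$scenario == lbl, ]
    success <- ab$annual_t > 0
    annual_total <- sum(ab$annual_t)
    area_ha_success <- sum(sites$area_m2[match(ab$site_id[success], sites$site_id)]) / 1e4
    vcu_site <- vcu_annual(ab$annual_t, g)
    cum_vcu <- cumulative_vcus(vcu_site, ab$years)
    window <- crediting_window(sum(vcu_site), start, end, price)
    social <- cumulative_benefit(annual_total, schedule, start, end)
    tibble::tibble(
      scenario = lbl,
      ef_pre = ef_pre_values[[lbl]],
      ef_post = ef_value(ef_post),
      annual_t = annual_total,
      success_area_ha = area_ha_success,
      per_hectare_t = if (area_ha_success > 0) annual_total / area_ha_success else 0,
      cumulative_t = sum(ab$cumulative_t),
      vcus_per_year = sum(vcu_site),
      cumulative_vcus = cum_vcu,
      revenue = credit_revenue(round(cum_vcu), price),
      window_credits = window$credits,
      window_revenue = window$revenue,
      social_benefit_cumulative = social$cumulative
    )
  }))

  statewide <- NULL
  if (!is.null(inventory)) {
    statewide <- dplyr::bind_rows(lapply(seq_len(nrow(summary)), function(i) {
      rate <- summary$per_hectare_t[i]
      abate <- statewide_abatement(rate, inventory)
      vcu <- vcu_annual(abate, g)
      social <- statewide_social_benefit(abate, schedule, start, end)
      tibble::tibble(
        scenario = summary$scenario[i],
        abatement_t_per_year = abate,
        vcus_per_year = vcu,
        revenue_per_year = credit_revenue(vcu, price),
        social_benefit_first_year = social$per_year$benefit[1],
        social_benefit_cumulative = social$cumulative
      )
    }))
  }

  list(sites = sites, abatement = abatement, summary = summary,
       statewide = statewide, schedule = schedule, gwp = g, price = price)
}
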