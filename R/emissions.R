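#' Construct an areal methane emission factor
#'
#' An emission factor assigns an areal methane emission rate (grams per
#' square meter per year) to a salinity regime. The published salt-marsh
#' factors are reported on a carbon-mass basis (gC m^-2 yr^-1); the VM0033
#' tiered post-restoration factors are reported as methane mass
#' (g CH4 m^-2 yr^-1). The `mass_basis` field records which, so that
#' scenarios mixing the two can be caught or corrected.
#'
#' @param value Emission rate, g m^-2 yr^-1, non-negative.
#' @param mass_basis `"carbon_as_reported"` or `"methane"`.
#' @param label Free-text label, e.g. `"geometric_mean"`.
#' @param salinity_min,salinity_max Salinity regime (psu) the factor applies
#'   to; informational.
#' @return An object of class `emission_factor`.
#' @export
emission_factor <- function(value,
                            mass_basis = c("carbon_as_reported", "methane"),
                            label = "",
                            salinity_min = -Inf, salinity_max = Inf) {
  mass_basis <- match.arg(mass_basis)
  if (!is.numeric(value) || length(value) != 1 || !is.finite(value) || value < 0) {
    stop("emission factor value must be a single non-negative number", call. = FALSE)
  }
  structure(
    list(value = value, mass_basis = mass_basis, label = label,
         salinity_min = salinity_min, salinity_max = salinity_max),
    class = "emission_factor"
  )
}

#' @export
print.emission_factor <- function(x, ...) {
  cat(sprintf("<emission_factor> %s: %.3g g/m2/yr (%s basis), salinity (%s, %s] psu\n",
              if (nzchar(x$label)) x$label else "unlabelled",
              x$value, x$mass_basis, format(x$salinity_min), format(x$salinity_max)))
  invisible(x)
}

#' Default emission-factor set
#'
#' The packaged factors: two alternative pre-restoration factors for
#' impaired marsh (salinity < 18 psu) — a cross-study geometric mean of
#' 19.4 gC m^-2 yr^-1 and a true mean of 41.6 gC m^-2 yr^-1 — the
#' post-restoration factor of 0.46 gC m^-2 yr^-1 for marsh above 18 psu,
#' and the more conservative VM0033 tiered post-restoration factors
#' (1.1 g CH4 m^-2 yr^-1 for 18--20 psu, 0.56 g CH4 m^-2 yr^-1 above
#' 20 psu).
#'
#' @return Named list of [emission_factor()] objects.
#' @export
default_emission_factors <- function() {
  list(
    geometric_mean   = emission_factor(19.4, "carbon_as_reported", "geometric_mean",
                                       salinity_max = 18),
    true_mean        = emission_factor(41.6, "carbon_as_reported", "true_mean",
                                       salinity_max = 18),
    post_restoration = emission_factor(0.46, "carbon_as_reported", "post_restoration",
                                       salinity_min = 18),
    vm0033_18_20     = emission_factor(1.1, "methane", "vm0033_18_20",
                                       salinity_min = 18, salinity_max = 20),
    vm0033_gt20      = emission_factor(0.56, "methane", "vm0033_gt20",
                                       salinity_min = 20)
  )
}

#' Select the post-restoration emission factor for a successful site
#'
#' Two schemes are supported: `"kroeger"` applies the single published
#' post-restoration factor (0.46 gC m^-2 yr^-1) to any site whose post
#' mean surpasses 18 psu; `"vm0033"` applies the standard's tiered factors
#' (1.1 g CH4 m^-2 yr^-1 for salinities in (18, 20], 0.56 for > 20 psu).
#' No post-restoration factor is defined at or below 18 psu — such sites
#' are not successful and contribute no abatement.
#'
#' @param post_mean Post-restoration pooled mean salinity (psu).
#' @param scheme `"kroeger"` or `"vm0033"`.
#' @return An [emission_factor()].
#' @export
select_post_ef <- function(post_mean, scheme = c("kroeger", "vm0033")) {
  scheme <- match.arg(scheme)
  if (!is.finite(post_mean)) stop("post_mean must be finite", call. = FALSE)
  if (post_mean <= salinity_threshold_psu) {
    stop("no post-restoration emission factor is defined for post_mean <= 18 psu ",
         "(site is not a successful restoration)", call. = FALSE)
  }
  efs <- default_emission_factors()
  if (scheme == "kroeger") {
    efs$post_restoration
  } else if (post_mean <= 20) {
    efs$vm0033_18_20
  } else {
    efs$vm0033_gt20
  }
}

ef_value <- function(ef) if (inherits(ef, "emission_factor")) ef$value else ef
ef_basis <- function(ef) if (inherits(ef, "emission_factor")) ef$mass_basis else NA_character_

#' Annual avoided methane emissions for one site
#'
#' The difference between the pre- and post-restoration emission factors,
#' applied uniformly over the restored area: `(ef_pre - ef_post) * area_m2
#' / 1e6` metric tons per year. In replication mode (the default) factor
#' values reported on a carbon-mass basis are used as printed, matching the
#' published accounting; setting `stoichiometric_correction = TRUE`
#' multiplies carbon-basis masses by 16/12 (the CH4:C mass ratio) to express
#' them as methane mass. Factors with mismatched mass bases are an error
#' unless the correction is on.
#'
#' @param ef_pre,ef_post Emission factors ([emission_factor()] objects or
#'   bare numerics in g m^-2 yr^-1; bare numerics are assumed to share a
#'   basis).
#' @param area_m2 Restored marsh area in square meters, > 0.
#' @param stoichiometric_correction Convert carbon-basis factors to methane
#'   mass (x 16/12)? Default `FALSE` (replication mode).
#' @return Avoided emissions in metric tons CH4 per year.
#' @export
annual_avoided <- function(ef_pre, ef_post, area_m2, stoichiometric_correction = FALSE) {
  if (!is.numeric(area_m2) || any(area_m2 <= 0)) {
    stop("area_m2 must be positive", call. = FALSE)
  }
  b_pre <- ef_basis(ef_pre); b_post <- ef_basis(ef_post)
  v_pre <- ef_value(ef_pre); v_post <- ef_value(ef_post)
  if (stoichiometric_correction) {
    if (identical(b_pre, "carbon_as_reported") || is.na(b_pre)) v_pre <- v_pre * 16 / 12
    if (identical(b_post, "carbon_as_reported") || is.na(b_post)) v_post <- v_post * 16 / 12
  } else if (!is.na(b_pre) && !is.na(b_post) && b_pre != b_post) {
    stop("emission factors have different mass bases (", b_pre, " vs ", b_post,
         "); enable stoichiometric_correction to put both on a methane-mass basis",
         call. = FALSE)
  }
  (v_pre - v_post) * area_m2 / 1e6
}

#' Avoided emissions per hectare
#'
#' @param annual_t Annual avoided emissions, metric tons CH4 per year.
#' @param area_ha Site area in hectares, > 0.
#' @return Metric tons CH4 per hectare per year. In replication mode this is
#'   area-independent and equals `(ef_pre - ef_post) / 100`.
#' @export
per_hectare_rate <- function(annual_t, area_ha) {
  if (!is.numeric(area_ha) || any(area_ha <= 0)) {
    stop("area_ha must be positive", call. = FALSE)
  }
  annual_t / area_ha
}

#' Cumulative avoided emissions over qualifying years
#'
#' @param annual_t Annual avoided emissions (unrounded), metric tons/yr.
#' @param years Count of qualifying post-restoration years, >= 0.
#' @return Metric tons CH4 over the qualifying years.
#' @export
cumulative_avoided <- function(annual_t, years) {
  if (any(years < 0)) stop("years must be non-negative", call. = FALSE)
  annual_t * years
}

#' Per-site avoided-emissions table under an emission-factor scenario
#'
#' Applies [annual_avoided()], [per_hectare_rate()] and
#' [cumulative_avoided()] across a site table. Sites whose outcome is not
#' `SUCCESS` contribute exactly zero.
#'
#' @param sites Tibble with columns `site_id`, `area_m2`, `outcome`,
#'   `qualifying_years` (e.g. from [table1_sites()] plus [classify_site()]).
#' @param ef_pre,ef_post Emission factors for the scenario.
#' @param label Scenario label recorded in the output.
#' @param stoichiometric_correction Passed to [annual_avoided()].
#' @return Tibble: `site_id`, `scenario`, `annual_t`, `per_hectare_t`,
#'   `cumulative_t`, `years`. All values are carried at full precision;
#'   rounding happens only in report rendering.
#' @export
avoided_emissions <- function(sites, ef_pre, ef_post, label = NULL,
                              stoichiometric_correction = FALSE) {
  required <- c("site_id", "area_m2", "outcome", "qualifying_years")
  missing <- setdiff(required, names(sites))
  if (length(missing)) {
    stop("sites table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(label)) {
    label <- paste0("EF_", format(ef_value(ef_pre)), "_", format(ef_value(ef_post)))
  }
  success <- sites$outcome == "SUCCESS"
  annual <- ifelse(
    success,
    annual_avoided(ef_pre, ef_post, sites$area_m2, stoichiometric_correction),
    0
  )
  years <- ifelse(success, sites$qualifying_years, 0L)
  tibble::tibble(
    site_id       = sites$site_id,
    scenario      = label,
    annual_t      = annual,
    per_hectare_t = annual / (sites$area_m2 / 1e4),
    cumulative_t  = cumulative_avoided(annual, years),
    years         = as.integer(years)
  )
}
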