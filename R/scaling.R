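#' Convert acres to hectares
#'
#' The regional tidal-restriction inventory reports area at acre precision;
#' dollar-level reproduction of the statewide estimates requires the
#' conversion used in the source accounting, 1 acre = 4,047 m^2 = 0.4047 ha.
#'
#' @param acres Area in acres.
#' @param m2_per_acre Square meters per acre; default 4047.
#' @return Hectares.
#' @export
acres_to_hectares <- function(acres, m2_per_acre = 4047) {
  acres * m2_per_acre / 1e4
}

#' Summarize a regional tidal-restriction marsh inventory
#'
#' A two-number summary of the restorable marsh area in a region: how many
#' marshes carry a tidal restriction above the effect threshold, and their
#' total area. The Massachusetts inventory used as the default is 475
#' marshes totalling 2,304 acres with a restriction-effect score above 0.5
#' (the score estimates the proportion of marsh lost, 0 = no effect,
#' 1 = severe).
#'
#' @param n_marshes Number of marshes, >= 0.
#' @param total_acres Total area in acres (authoritative; converted with
#'   [acres_to_hectares()]). Give either this or `total_ha`.
#' @param total_ha Total area in hectares, if already converted.
#' @param effect_threshold Restriction-effect cutoff in `[0, 1]`; default 0.5.
#' @param source_label Free-text provenance label.
#' @return Object of class `marsh_inventory` with `n_marshes`, `total_ha`,
#'   `effect_threshold`, `source_label`.
#' @export
marsh_inventory <- function(n_marshes, total_acres = NULL, total_ha = NULL,
                            effect_threshold = 0.5, source_label = "") {
  if (is.null(total_ha) == is.null(total_acres)) {
    stop("give exactly one of total_acres or total_ha", call. = FALSE)
  }
  if (is.null(total_ha)) total_ha <- acres_to_hectares(total_acres)
  if (total_ha <= 0 && n_marshes > 0) {
    stop("inventory area must be positive", call. = FALSE)
  }
  if (effect_threshold < 0 || effect_threshold > 1) {
    stop("effect_threshold must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(n_marshes = n_marshes, total_ha = total_ha,
         effect_threshold = effect_threshold, source_label = source_label),
    class = "marsh_inventory"
  )
}

#' @export
print.marsh_inventory <- function(x, ...) {
  cat(sprintf("<marsh_inventory> %d marshes, %.1f ha, effect > %.2f%s\n",
              x$n_marshes, x$total_ha, x$effect_threshold,
              if (nzchar(x$source_label)) paste0(" [", x$source_label, "]") else ""))
  invisible(x)
}

#' Default Massachusetts tidal-restriction inventory
#'
#' 475 marshes, 2,304 acres (932.4 ha), restriction-effect score > 0.5.
#'
#' @return A [marsh_inventory()].
#' @export
ma_inventory <- function() {
  marsh_inventory(475, total_acres = 2304, effect_threshold = 0.5,
                  source_label = "MA tidal restriction atlas")
}

#' Build an inventory summary from a per-marsh table
#'
#' Filters a per-marsh table (`marsh_id`, `area_ha`, `effect_score`) to
#' restrictions with effect strictly above the threshold and sums their
#' area.
#'
#' @param marshes Data frame with columns `marsh_id`, `area_ha`,
#'   `effect_score`.
#' @param effect_threshold Cutoff in `[0, 1]`; marshes with
#'   `effect_score > effect_threshold` are retained. Default 0.5.
#' @param source_label Provenance label.
#' @return A [marsh_inventory()] over the retained marshes.
#' @export
inventory_from_table <- function(marshes, effect_threshold = 0.5, source_label = "") {
  required <- c("marsh_id", "area_ha", "effect_score")
  missing <- setdiff(required, names(marshes))
  if (length(missing)) {
    stop("marsh table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  keep <- marshes$effect_score > effect_threshold
  marsh_inventory(sum(keep), total_ha = sum(marshes$area_ha[keep]),
                  effect_threshold = effect_threshold, source_label = source_label)
}

#' Statewide avoided-methane upper bound
#'
#' Applies a per-hectare abatement rate uniformly across the inventory
#' area, giving the upper-bound statewide abatement were every restriction
#' successfully remediated.
#'
#' @param per_ha_rate Abatement rate, metric tons CH4 per hectare per year,
#'   >= 0 (e.g. from [per_hectare_rate()]).
#' @param inventory A [marsh_inventory()].
#' @return Metric tons CH4 per year.
#' @export
statewide_abatement <- function(per_ha_rate, inventory) {
  if (per_ha_rate < 0) stop("per_ha_rate must be non-negative", call. = FALSE)
  stopifnot(inherits(inventory, "marsh_inventory"))
  per_ha_rate * inventory$total_ha
}

#' Statewide social benefit
#'
#' Delegates to [cumulative_benefit()] with the statewide abatement.
#'
#' @param abatement_t Statewide abatement, metric tons CH4 per year.
#' @param schedule `scm_schedule` at one discount rate.
#' @param start,end Valuation window, defaults 2021--2050.
#' @return As [cumulative_benefit()].
#' @export
statewide_social_benefit <- function(abatement_t, schedule, start = 2021, end = 2050) {
  cumulative_benefit(abatement_t, schedule, start, end)
}

#' Apply a restoration success rate to a statewide estimate
#'
#' The all-sites estimate is an extreme upper bound: of the monitored
#' projects only one- to two-thirds achieved the salinity change indicating
#' methane abatement. Every component of the estimate scales
#' multiplicatively with the assumed success rate.
#'
#' @param estimate Named numeric vector (or single number) of statewide
#'   quantities (abatement, revenue, social benefit, ...).
#' @param success_rate Fraction in `[0, 1]`.
#' @return `estimate * success_rate`, names preserved.
#' @export
success_adjusted <- function(estimate, success_rate) {
  if (!is.numeric(success_rate) || length(success_rate) != 1 ||
      success_rate < 0 || success_rate > 1) {
    stop("success_rate must be a single value in [0, 1]", call. = FALSE)
  }
  estimate * success_rate
}
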