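#' @importFrom rlang .data
#' @importFrom stats sd setNames rnorm rlnorm rbeta runif
NULL

#' Soil depth classes used in marsh salinity monitoring
#'
#' Salinity is measured in discrete soil depth bands: shallow (5--20 cm),
#' medium (35--50 cm) and deep (65--80 cm).
#'
#' @format Named character vector mapping class name to its centimeter band.
#' @export
depth_classes <- c(
  shallow = "5-20cm",
  medium  = "35-50cm",
  deep    = "65-80cm"
)

#' Default salinity threshold separating methanogenic from non-methanogenic marsh
#'
#' Above roughly 18 psu, sulfate reduction outcompetes methanogenesis and
#' a previously freshening salt marsh effectively ceases methane production.
#' All classification and qualifying-year logic defaults to this value.
#'
#' @export
salinity_threshold_psu <- 18

#' Read a salinity observation table from CSV
#'
#' Reads field salinity measurements into a validated tibble with columns
#' `site_id`, `date`, `transect_id`, `depth_class` and `salinity_psu`.
#' Files whose columns are named or ordered differently can be adapted with
#' `col_map`.
#'
#' @param path Path to a comma-separated, UTF-8, headered CSV file.
#' @param col_map Optional named character vector mapping the canonical
#'   column names to the names used in the file, e.g.
#'   `c(salinity_psu = "sal", date = "sampled_on")`. Unmapped canonical
#'   names are looked up verbatim.
#' @param date_format Optional date format string (see [base::strptime()]).
#'   ISO-8601 (`"%Y-%m-%d"`) is assumed when `NULL`.
#' @return A tibble of salinity observations, one row per measurement.
#'   Negative or unparseable salinity values and unparseable dates are
#'   rejected with an error naming the offending row numbers.
#' @export
read_salinity_observations <- function(path, col_map = NULL, date_format = NULL) {
  if (!file.exists(path)) {
    stop("observation file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("site_id", "date", "transect_id", "depth_class", "salinity_psu")
  lookup <- setNames(required, required)
  if (!is.null(col_map)) {
    bad <- setdiff(names(col_map), required)
    if (length(bad)) {
      stop("unknown canonical column(s) in col_map: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    lookup[names(col_map)] <- unname(col_map)
  }
  missing <- lookup[!lookup %in% names(raw)]
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  obs <- tibble::tibble(
    site_id      = raw[[lookup[["site_id"]]]],
    date         = raw[[lookup[["date"]]]],
    transect_id  = raw[[lookup[["transect_id"]]]],
    depth_class  = raw[[lookup[["depth_class"]]]],
    salinity_psu = raw[[lookup[["salinity_psu"]]]]
  )
  validate_observations(obs, date_format = date_format)
}

#' Validate and normalize a salinity observation table
#'
#' Coerces dates and salinities, enforces the non-negative salinity invariant
#' and the known depth classes. Used by [read_salinity_observations()] and
#' available directly for observations built in code.
#'
#' @param obs Data frame with columns `site_id`, `date`, `transect_id`,
#'   `depth_class`, `salinity_psu`.
#' @param date_format Optional date format string; ISO-8601 when `NULL`.
#' @return A tibble with `date` as `Date` and `salinity_psu` numeric.
#' @export
validate_observations <- function(obs, date_format = NULL) {
  obs <- tibble::as_tibble(obs)
  required <- c("site_id", "date", "transect_id", "depth_class", "salinity_psu")
  missing <- setdiff(required, names(obs))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!inherits(obs$date, "Date")) {
    fmt <- if (is.null(date_format)) "%Y-%m-%d" else date_format
    parsed <- as.Date(as.character(obs$date), format = fmt)
    bad <- which(is.na(parsed) & !is.na(obs$date))
    if (length(bad)) {
      stop("unparseable date(s) at row(s): ", paste(utils::head(bad, 10), collapse = ", "),
           call. = FALSE)
    }
    obs$date <- parsed
  }
  sal <- suppressWarnings(as.numeric(obs$salinity_psu))
  bad <- which(is.na(sal) & !is.na(obs$salinity_psu))
  if (length(bad)) {
    stop("unparseable salinity value(s) at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  neg <- which(sal < 0)
  if (length(neg)) {
    stop("negative salinity at row(s): ", paste(utils::head(neg, 10), collapse = ", "),
         "; salinity must be >= 0 psu", call. = FALSE)
  }
  obs$salinity_psu <- sal
  unknown <- setdiff(unique(obs$depth_class), names(depth_classes))
  if (length(unknown)) {
    stop("unknown depth class(es): ", paste(unknown, collapse = ", "),
         " (expected ", paste(names(depth_classes), collapse = "/"), ")", call. = FALSE)
  }
  obs
}

#' Summarize salinity observations around a restoration date
#'
#' Computes the pooled (or stratified) mean salinity and its standard error
#' for the pre- or post-restoration window. The default pools every
#' observation in the window regardless of transect, depth and season;
#' the mean is the plain arithmetic mean and the standard error is the
#' sample standard deviation divided by sqrt(n). Observations dated strictly
#' before the restoration date are "pre"; observations on or after it are
#' "post".
#'
#' @param obs Observation tibble (see [read_salinity_observations()]).
#' @param restoration_date Restoration date (`Date` or ISO-8601 string).
#' @param window `"pre"` or `"post"`.
#' @param stratify_by `"none"` (pooled, default), `"depth"` or `"year"`.
#' @return A tibble with columns `window`, `stratum`, `mean_psu`, `se_psu`
#'   and `n`; one row when unstratified. An empty window is an error, never
#'   a silent zero.
#' @export
summarize_salinity <- function(obs, restoration_date,
                               window = c("pre", "post"),
                               stratify_by = c("none", "depth", "year")) {
  window <- match.arg(window)
  stratify_by <- match.arg(stratify_by)
  obs <- validate_observations(obs)
  restoration_date <- as.Date(restoration_date)
  keep <- if (window == "pre") obs$date < restoration_date else obs$date >= restoration_date
  sub <- obs[keep & !is.na(obs$date), , drop = FALSE]
  if (nrow(sub) == 0) {
    stop("no observations in the ", window, "-restoration window", call. = FALSE)
  }
  sub$stratum <- switch(stratify_by,
    none  = "all",
    depth = as.character(sub$depth_class),
    year  = as.character(as.integer(format(sub$date, "%Y")))
  )
  out <- dplyr::summarise(
    dplyr::group_by(sub, .data$stratum),
    mean_psu = mean(.data$salinity_psu),
    se_psu   = if (dplyr::n() > 1) sd(.data$salinity_psu) / sqrt(dplyr::n()) else 0,
    n        = dplyr::n(),
    .groups  = "drop"
  )
  out <- dplyr::arrange(out, .data$stratum)
  tibble::tibble(window = window, out)
}

#' Classify a restoration outcome against the salinity threshold
#'
#' A restoration is a `SUCCESS` only if the site was impaired before
#' (pre-restoration mean strictly below the threshold) and the
#' post-restoration mean strictly surpassed the threshold. An impaired site
#' whose post mean did not surpass the threshold is
#' `FAILED_BELOW_THRESHOLD`; a site whose pre mean was already at or above
#' the threshold was never impaired (`NOT_IMPAIRED`) and contributes no
#' avoided emissions. Boundary equality therefore resolves away from
#' `SUCCESS` in both comparisons.
#'
#' @param pre_mean,post_mean Pooled mean salinities (psu); vectorized.
#' @param threshold Salinity threshold in psu (default 18).
#' @return Character vector of outcome categories.
#' @export
classify_site <- function(pre_mean, post_mean, threshold = salinity_threshold_psu) {
  if (any(!is.finite(pre_mean)) || any(!is.finite(post_mean))) {
    stop("pre_mean and post_mean must be finite", call. = FALSE)
  }
  dplyr::case_when(
    pre_mean >= threshold ~ "NOT_IMPAIRED",
    post_mean > threshold ~ "SUCCESS",
    TRUE                  ~ "FAILED_BELOW_THRESHOLD"
  )
}

#' Post-restoration qualifying years
#'
#' Computes per-calendar-year mean salinities for the post-restoration
#' window and flags the years whose annual mean surpasses the threshold.
#' Restored marshes can show a lag phase: years immediately after
#' restoration whose salinity has not yet risen above threshold. Such years
#' are excluded from cumulative abatement accounting, since methane
#' production was still possible.
#'
#' @inheritParams summarize_salinity
#' @param threshold Salinity threshold in psu (default 18).
#' @return Tibble with columns `year`, `mean_psu`, `n`, `qualifies`, ordered
#'   by year. The qualifying-year count is `sum(result$qualifies)`.
#' @export
qualifying_years <- function(obs, restoration_date, threshold = salinity_threshold_psu) {
  ann <- summarize_salinity(obs, restoration_date, window = "post", stratify_by = "year")
  tibble::tibble(
    year      = as.integer(ann$stratum),
    mean_psu  = ann$mean_psu,
    n         = ann$n,
    qualifies = ann$mean_psu > threshold
  )
}

#' One-row site summary: means, outcome, qualifying years
#'
#' Convenience wrapper running the standard aggregation for a single site:
#' pooled pre/post means with standard errors, outcome classification and
#' the qualifying-year count.
#'
#' @inheritParams qualifying_years
#' @param site_id Optional site identifier carried into the output.
#' @return One-row tibble: `site_id`, `pre_mean_psu`, `pre_se_psu`, `pre_n`,
#'   `post_mean_psu`, `post_se_psu`, `post_n`, `outcome`, `qualifying_years`.
#' @export
site_summary <- function(obs, restoration_date, threshold = salinity_threshold_psu,
                         site_id = NA_character_) {
  pre  <- summarize_salinity(obs, restoration_date, "pre")
  post <- summarize_salinity(obs, restoration_date, "post")
  qy   <- qualifying_years(obs, restoration_date, threshold)
  tibble::tibble(
    site_id = site_id,
    pre_mean_psu = pre$mean_psu, pre_se_psu = pre$se_psu, pre_n = pre$n,
    post_mean_psu = post$mean_psu, post_se_psu = post$se_psu, post_n = post$n,
    outcome = classify_site(pre$mean_psu, post$mean_psu, threshold),
    qualifying_years = sum(qy$qualifies)
  )
}
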