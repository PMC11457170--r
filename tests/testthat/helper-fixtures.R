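# In-code fixture builders shared across the suite.

# A minimal observation tibble; vectors are recycled to the longest length.
make_obs <- function(salinity,
                     date = "2000-06-15",
                     site_id = "site_a",
                     transect_id = "T1",
                     depth_class = "shallow") {
  tibble::tibble(
    site_id = site_id,
    date = as.Date(date),
    transect_id = transect_id,
    depth_class = depth_class,
    salinity_psu = salinity
  )
}

# Write an observation data frame to a temp CSV and return the path.
write_obs_csv <- function(df, col_order = NULL) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  if (!is.null(col_order)) df <- df[, col_order]
  readr::write_csv(df, path)
  path
}

# Canonical two-site success fixture mirroring the monitored-site summary
# table: only these two sites are successful restorations.
success_sites <- function() {
  sites <- table1_sites()
  sites$outcome <- classify_site(sites$pre_mean_psu, sites$post_mean_psu)
  sites$qualifying_years <- sites$post_restoration_years
  sites
}
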