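test_that("CSV round-trip preserves observations, with and without column mapping", {
  df <- make_obs(c(10.5, 12.0, 14.25), date = c("2001-03-01", "2001-06-01", "2001-09-01"),
                 depth_class = c("shallow", "medium", "deep"))
  path <- write_obs_csv(df)
  obs <- read_salinity_observations(path)
  expect_equal(nrow(obs), 3)
  expect_equal(obs$salinity_psu, df$salinity_psu)
  expect_s3_class(obs$date, "Date")

  # shuffled column order + renamed salinity column, adapted via col_map
  df2 <- df
  names(df2)[names(df2) == "salinity_psu"] <- "sal"
  path2 <- write_obs_csv(df2, col_order = c("sal", "depth_class", "site_id",
                                            "transect_id", "date"))
  obs2 <- read_salinity_observations(path2, col_map = c(salinity_psu = "sal"))
  expect_equal(dplyr::arrange(obs2, date), dplyr::arrange(obs, date))
})

test_that("ingest rejects malformed input with informative errors", {
  df <- make_obs(c(10, -2, 12), date = c("2001-03-01", "2001-06-01", "2001-09-01"))
  expect_error(validate_observations(df), "negative salinity.*2")

  df_bad_sal <- df
  df_bad_sal$salinity_psu <- c("10", "oops", "12")
  expect_error(validate_observations(df_bad_sal), "unparseable salinity.*2")

  df_bad_depth <- make_obs(10, depth_class = "abyssal")
  expect_error(validate_observations(df_bad_depth), "unknown depth class")

  path <- write_obs_csv(make_obs(10)[, -5])
  expect_error(read_salinity_observations(path), "missing required column")
  expect_error(read_salinity_observations(tempfile()), "not found")
})

test_that("custom date formats are honoured and bad dates rejected", {
  df <- make_obs(c(10, 11))
  df$date <- c("03/15/2001", "06/15/2001")
  obs <- validate_observations(df, date_format = "%m/%d/%Y")
  expect_equal(obs$date, as.Date(c("2001-03-15", "2001-06-15")))
  df$date <- c("03/15/2001", "junk")
  expect_error(validate_observations(df, date_format = "%m/%d/%Y"), "unparseable date")
})

test_that("pooled summary is the plain arithmetic mean with SE = sd/sqrt(n)", {
  vals_pre <- c(9.5, 10.5, 11.0, 8.6)
  vals_post <- c(19.5, 20.5)
  df <- dplyr::bind_rows(
    make_obs(vals_pre, date = "2002-05-01",
             depth_class = c("shallow", "medium", "deep", "shallow")),
    make_obs(vals_post, date = "2004-05-01", depth_class = c("shallow", "deep"))
  )
  pre <- summarize_salinity(df, "2003-11-01", "pre")
  expect_equal(pre$mean_psu, mean(vals_pre))
  expect_equal(pre$se_psu, sd(vals_pre) / sqrt(length(vals_pre)))
  expect_equal(pre$n, length(vals_pre))

  post <- summarize_salinity(df, "2003-11-01", "post")
  expect_equal(post$mean_psu, mean(vals_post))

  # single observation: SE is 0, not NA
  one <- summarize_salinity(make_obs(18), "1999-01-01", "post")
  expect_equal(one$mean_psu, 18)
  expect_equal(one$se_psu, 0)

  # observations on the restoration date belong to the post window
  on_date <- summarize_salinity(make_obs(c(5, 25), date = c("2003-11-01", "2002-01-01")),
                                "2003-11-01", "post")
  expect_equal(on_date$mean_psu, 5)

  expect_error(summarize_salinity(make_obs(10, date = "2005-01-01"), "2003-11-01", "pre"),
               "no observations")
})

test_that("depth stratification isolates a shallow-only salinity shift", {
  base <- c(shallow = 12, medium = 14, deep = 15)
  pre <- dplyr::bind_rows(lapply(names(base), function(d) {
    make_obs(rep(base[[d]], 3), date = "2001-06-01", depth_class = d)
  }))
  post <- pre
  post$date <- as.Date("2005-06-01")
  post$salinity_psu[post$depth_class == "shallow"] <- 21
  df <- dplyr::bind_rows(pre, post)

  s_pre <- summarize_salinity(df, "2003-01-01", "pre", stratify_by = "depth")
  s_post <- summarize_salinity(df, "2003-01-01", "post", stratify_by = "depth")
  get <- function(s, d) s$mean_psu[s$stratum == d]
  expect_equal(get(s_post, "shallow"), 21)
  expect_equal(get(s_pre, "shallow"), 12)
  expect_equal(get(s_post, "deep"), get(s_pre, "deep"))
  expect_equal(get(s_post, "medium"), get(s_pre, "medium"))
})

test_that("outcome classification follows the strict 18 psu conventions", {
  # printed site means: impaired->recovered, impaired->still fresh, never impaired
  expect_equal(classify_site(10.2, 19.0), "SUCCESS")
  expect_equal(classify_site(12.6, 9.8), "FAILED_BELOW_THRESHOLD")
  expect_equal(classify_site(27.4, 25.7), "NOT_IMPAIRED")
  expect_equal(classify_site(18.3, 23.7), "NOT_IMPAIRED")  # pre at/above threshold
  # boundary equality resolves away from SUCCESS ("surpassed" is strict)
  expect_equal(classify_site(17.9, 18.0), "FAILED_BELOW_THRESHOLD")
  expect_equal(classify_site(18.0, 25.0), "NOT_IMPAIRED")
  expect_error(classify_site(NA_real_, 19), "finite")
})

test_that("classification of the six monitored sites matches the published outcomes", {
  sites <- success_sites()
  expect_equal(
    sites$outcome[match(c("eastern_point", "mill_pond", "cedar_point",
                          "seaview_street", "town_farm", "conomo_point"),
                        sites$site_id)],
    c("SUCCESS", "SUCCESS", "FAILED_BELOW_THRESHOLD",
      "FAILED_BELOW_THRESHOLD", "NOT_IMPAIRED", "NOT_IMPAIRED")
  )
})

test_that("classification is invariant to observation order and duplication", {
  gen <- generate_site(site_scenario(true_pre_mean = 12, true_post_mean = 21,
                                     observation_sd = 2), seed = 11)
  obs <- gen$observations
  rd <- gen$site$restoration_date
  base <- site_summary(obs, rd)

  shuffled <- obs[sample.int(nrow(obs)), ]
  expect_equal(site_summary(shuffled, rd)$outcome, base$outcome)
  expect_equal(site_summary(shuffled, rd)$pre_mean_psu, base$pre_mean_psu)

  doubled <- dplyr::bind_rows(obs, obs)
  expect_equal(site_summary(doubled, rd)$outcome, base$outcome)
  expect_equal(site_summary(doubled, rd)$pre_mean_psu, base$pre_mean_psu)
})

test_that("qualifying years follow annual means and shrink as the threshold rises", {
  # 2 lag years below threshold then qualifying years above
  sc <- site_scenario(true_pre_mean = 12, true_post_mean = 21, observation_sd = 0.5,
                      monitoring_start = 2000, monitoring_end = 2010,
                      restoration_date = "2004-01-01", lag_years = 2)
  gen <- generate_site(sc, seed = 7)
  qy <- qualifying_years(gen$observations, gen$site$restoration_date)
  expect_equal(sum(qy$qualifies), gen$truth$intended_qualifying_years)
  expect_equal(sum(qy$qualifies), 5)  # 2004..2010 minus 2 lag years
  expect_equal(qy$year, 2004:2010)

  # monotone non-increasing in the threshold
  counts <- vapply(c(10, 15, 18, 20, 25), function(th) {
    sum(qualifying_years(gen$observations, gen$site$restoration_date, th)$qualifies)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))

  # all post years below threshold -> no qualifying years
  fresh <- generate_site(site_scenario(true_pre_mean = 10, true_post_mean = 12,
                                       observation_sd = 0.5), seed = 3)
  expect_equal(sum(qualifying_years(fresh$observations,
                                    fresh$site$restoration_date)$qualifies), 0)
})
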