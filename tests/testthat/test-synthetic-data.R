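test_that("generation is deterministic under seed and leaves global RNG state alone", {
  sc <- site_scenario(true_pre_mean = 10.2, true_post_mean = 19,
                      observation_sd = 2, seasonal_amplitude = 1.5,
                      depth_offsets = c(shallow = 1, deep = -1))
  a <- generate_site(sc, seed = 42)
  b <- generate_site(sc, seed = 42)
  expect_identical(a$observations, b$observations)
  c <- generate_site(sc, seed = 43)
  expect_false(identical(a$observations$salinity_psu, c$observations$salinity_psu))

  set.seed(99); before <- runif(3)
  set.seed(99); invisible(generate_site(sc, seed = 1)); after <- runif(3)
  expect_identical(before, after)
})

test_that("the noiseless limit recovers the true means exactly", {
  sc <- site_scenario(true_pre_mean = 10.2, true_post_mean = 19,
                      observation_sd = 0, n_per_year = 1, transects = 1)
  gen <- generate_site(sc, seed = 1)
  s <- site_summary(gen$observations, gen$site$restoration_date)
  expect_equal(s$pre_mean_psu, 10.2)
  expect_equal(s$post_mean_psu, 19)
  expect_equal(s$outcome, "SUCCESS")
})

test_that("classification recovers the generator's intended outcome", {
  cases <- list(
    list(pre = 10.2, post = 19.0, want = "SUCCESS"),        # impaired -> recovered
    list(pre = 27.4, post = 25.7, want = "NOT_IMPAIRED"),   # never impaired
    list(pre = 12.6, post = 9.8, want = "FAILED_BELOW_THRESHOLD")
  )
  for (cs in cases) {
    sc <- site_scenario(true_pre_mean = cs$pre, true_post_mean = cs$post,
                        observation_sd = 1)
    gen <- generate_site(sc, seed = 5)
    expect_equal(gen$truth$intended_outcome, cs$want)
    s <- site_summary(gen$observations, gen$site$restoration_date)
    expect_equal(s$outcome, cs$want)
  }
})

test_that("scenario validation rejects inconsistent configurations", {
  expect_error(site_scenario(true_pre_mean = 10, true_post_mean = 15, lag_years = 2),
               "inconsistent scenario")
  expect_error(site_scenario(true_pre_mean = 10, true_post_mean = 21, lag_years = 99),
               "exceeds the post-restoration monitoring span")
  expect_error(site_scenario(true_pre_mean = 10, true_post_mean = 21,
                             restoration_date = "1990-06-01"),
               "inside the monitoring span")
  expect_error(site_scenario(true_pre_mean = 10, true_post_mean = 21,
                             depth_offsets = c(benthic = 1)),
               "depth_offsets")
})

test_that("classification accuracy >= 95% when true means sit > 3 SE from threshold", {
  # SE of the pooled post mean: sd / sqrt(n_post). With sd = 3 and
  # 12 post years x 3 transects x 3 depths x 2 per year, n is large and
  # |mean - 18| = 3 psu is far beyond 3 SE on both sides of the threshold.
  sc <- site_scenario(true_pre_mean = 15, true_post_mean = 21,
                      observation_sd = 3, n_per_year = 2,
                      monitoring_start = 2000, monitoring_end = 2015,
                      restoration_date = "2004-01-01")
  n_rep <- 200
  hits <- vapply(seq_len(n_rep), function(i) {
    gen <- generate_site(sc, seed = i)
    s <- site_summary(gen$observations, gen$site$restoration_date)
    identical(s$outcome, gen$truth$intended_outcome)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("estimated means are unbiased within Monte-Carlo error", {
  sc <- site_scenario(true_pre_mean = 12, true_post_mean = 21,
                      observation_sd = 3, n_per_year = 2)
  n_rep <- 200
  post_means <- vapply(seq_len(n_rep), function(i) {
    gen <- generate_site(sc, seed = 1000 + i)
    summarize_salinity(gen$observations, gen$site$restoration_date, "post")$mean_psu
  }, numeric(1))
  mc_se <- sd(post_means) / sqrt(n_rep)
  expect_lt(abs(mean(post_means) - 21), 4 * mc_se)
})

test_that("lag years are pulled below threshold and excluded from qualifying counts", {
  sc <- site_scenario(true_pre_mean = 10, true_post_mean = 22,
                      observation_sd = 0.5,
                      monitoring_start = 2000, monitoring_end = 2012,
                      restoration_date = "2003-01-01", lag_years = 3)
  gen <- generate_site(sc, seed = 8)
  qy <- qualifying_years(gen$observations, gen$site$restoration_date)
  expect_false(any(qy$qualifies[qy$year %in% 2003:2005]))
  expect_equal(sum(qy$qualifies), gen$truth$intended_qualifying_years)
  expect_equal(gen$truth$intended_qualifying_years, 10 - 3)
})

test_that("end-to-end: a generated SUCCESS site reproduces the closed-form abatement", {
  sc <- site_scenario(true_pre_mean = 10.2, true_post_mean = 19,
                      observation_sd = 2, area_m2 = 10955,
                      monitoring_start = 2000, monitoring_end = 2015,
                      restoration_date = "2003-11-01")
  gen <- generate_site(sc, seed = 21)
  s <- site_summary(gen$observations, gen$site$restoration_date)
  expect_equal(s$outcome, "SUCCESS")
  ab <- annual_avoided(19.4, 0.46, gen$site$area_m2)
  # abatement depends on area and classification only, never the noise
  expect_equal(ab, (19.4 - 0.46) * 10955 / 1e6)
})

test_that("the packaged six-site table matches the printed metadata", {
  sites <- table1_sites()
  expect_equal(nrow(sites), 6)
  expect_equal(sites$area_m2[sites$site_id == "mill_pond"], 161880)
  expect_equal(sort(sites$area_m2),
               sort(c(54197, 10955, 12869, 97128, 12141, 161880)))
  expect_equal(sites$area_ha, sites$area_m2 / 1e4)
  success <- sites[classify_site(sites$pre_mean_psu, sites$post_mean_psu) == "SUCCESS", ]
  expect_equal(round(sum(success$area_ha), 1), 17.3)
  expect_equal(success$post_restoration_years[match(c("eastern_point", "mill_pond"),
                                                    success$site_id)], c(12L, 11L))
})

test_that("synthetic inventories filter exactly to their ground truth", {
  inv <- generate_inventory(100, seed = 31)
  filt <- inventory_from_table(inv, 0.5)
  expect_equal(filt$n_marshes, attr(inv, "truth_filtered_n"))
  expect_equal(filt$total_ha, attr(inv, "truth_filtered_ha"))

  expect_identical(generate_inventory(50, seed = 4), generate_inventory(50, seed = 4))
  expect_equal(inventory_from_table(inv, 1)$n_marshes, 0)     # exclusive threshold
  expect_equal(inventory_from_table(inv, 0)$n_marshes, 100)   # all retained
  expect_equal(nrow(generate_inventory(0, seed = 1)), 0)
})
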