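test_that("proportional allocation sits on the diagonal with CI zero", {
  set.seed(101)
  pop <- stats::rlnorm(6, 13, 1)
  panel <- toy_panel(population = pop, area = stats::rlnorm(6, 9, 1),
                     gdp = stats::rlnorm(6, 11, 0.5),
                     values = list(x = 0.004 * pop))
  res <- concentration_curve(panel, "x")
  expect_equal(res$area_S, 0.5, tolerance = 1e-12)
  expect_equal(res$ci, 0, tolerance = 1e-12)
  expect_equal(res$points$X, res$points$Y, tolerance = 1e-12)
})

test_that("the two-region worked example gives S = 0.375 and CI = 0.25", {
  panel <- toy_panel(population = c(1, 1), area = c(1, 1), gdp = c(1, 2),
                     values = list(x = c(0.25, 0.75)))
  res <- concentration_curve(panel, "x")
  expect_equal(res$points$X, c(0, 0.5, 1))
  expect_equal(res$points$Y, c(0, 0.25, 1))
  expect_equal(res$area_S, 0.375)
  expect_equal(res$ci, 0.25)

  # reversing the economic ordering flips the sign exactly
  rev <- toy_panel(population = c(1, 1), area = c(1, 1), gdp = c(2, 1),
                   values = list(x = c(0.25, 0.75)))
  expect_equal(concentration_curve(rev, "x")$ci, -0.25)
})

test_that("curve endpoints, monotonicity and the S/CI identity always hold", {
  set.seed(111)
  for (rep in 1:20) {
    panel <- random_panel(sample(3:15, 1))
    res <- concentration_curve(panel, "x")
    pts <- res$points
    expect_equal(pts$X[1], 0)
    expect_equal(pts$Y[1], 0)
    expect_equal(pts$X[nrow(pts)], 1, tolerance = 1e-12)
    expect_equal(pts$Y[nrow(pts)], 1, tolerance = 1e-12)
    expect_true(all(diff(pts$X) >= 0) && all(diff(pts$Y) >= 0))
    expect_equal(res$ci, 2 * (0.5 - res$area_S), tolerance = 1e-12)
    expect_true(res$ci > -1 && res$ci < 1)
  }
})

test_that("trapezoid CI equals the covariance-form oracle and is scale-free", {
  set.seed(121)
  for (rep in 1:200) {
    df <- as.data.frame(random_panel(sample(3:15, 1)))
    panel <- regional_panel(df, indicators = indicator_schema("x"))
    ci <- concentration_curve(panel, "x")$ci
    expect_equal(ci, ci_covariance_oracle(df$population, df$x,
                                          df$gdp_per_capita),
                 tolerance = 1e-9)

    df2 <- df; df2$x <- df2$x * 53.1
    panel2 <- regional_panel(df2, indicators = indicator_schema("x"))
    expect_equal(concentration_curve(panel2, "x")$ci, ci, tolerance = 1e-9)
  }
})

test_that("reversal of the GDP ordering maps CI to -CI", {
  set.seed(131)
  for (rep in 1:20) {
    df <- as.data.frame(random_panel(sample(3:10, 1)))
    panel <- regional_panel(df, indicators = indicator_schema("x"))
    df_rev <- df
    # monotone decreasing transform preserves the partition, reverses ranks
    df_rev$gdp_per_capita <- max(df$gdp_per_capita) + min(df$gdp_per_capita) -
      df$gdp_per_capita
    panel_rev <- regional_panel(df_rev, indicators = indicator_schema("x"))
    expect_equal(concentration_curve(panel_rev, "x")$ci,
                 -concentration_curve(panel, "x")$ci, tolerance = 1e-12)
  }
})

test_that("splitting a region into identical halves leaves S and CI alone", {
  set.seed(141)
  df <- as.data.frame(random_panel(7))
  panel <- regional_panel(df, indicators = indicator_schema("x"))
  base <- concentration_curve(panel, "x")

  half <- df[c(seq_len(7), 4), ]
  half[c(4, 8), c("population", "area", "x")] <-
    half[c(4, 8), c("population", "area", "x")] / 2
  half$region_id[8] <- "r4b"
  half$region_name[8] <- "r4b"
  panel2 <- regional_panel(half, indicators = indicator_schema("x"))
  split <- concentration_curve(panel2, "x")
  expect_equal(split$area_S, base$area_S, tolerance = 1e-12)
  expect_equal(split$ci, base$ci, tolerance = 1e-12)
})

test_that("zero resource totals are undefined rather than zero", {
  panel <- toy_panel(c(1, 1), c(1, 1), c(1, 2), list(x = c(0, 0)))
  expect_error(concentration_curve(panel, "x"),
               class = "hrequity_undefined_statistic")
})

test_that("the CI time series covers every indicator-year in range", {
  panel <- generate_panel(yeb_preset(seed = 3))
  long <- ci_timeseries(panel, wide = FALSE)
  expect_equal(nrow(long), 7 * 10)
  expect_true(all(long$ci > -1 & long$ci < 1))

  wide <- ci_timeseries(panel)
  expect_equal(dim(wide), c(7, 11))
  expect_equal(wide$general_practitioners[wide$year == 2019],
               long$ci[long$year == 2019 &
                         long$indicator == "general_practitioners"])

  err <- tryCatch(ci_timeseries(panel, years = c(2019, 2031, 2044)),
                  error = identity)
  expect_s3_class(err, "hrequity_validation_error")
  expect_match(conditionMessage(err), "2031, 2044")

  # a static panel gives the same CI every year
  df <- as.data.frame(random_panel(5, year = 2013))
  static <- do.call(rbind, lapply(2013:2015, function(y) {
    df$year <- y; df
  }))
  sp <- regional_panel(static, indicators = indicator_schema("x"))
  cis <- ci_timeseries(sp, wide = FALSE)
  expect_equal(length(unique(round(cis$ci, 12))), 1)

  pts <- concentration_points(panel, indicators = "beds", years = 2019)
  expect_equal(nrow(pts), 12)
  expect_equal(pts$order, 0:11)
})
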