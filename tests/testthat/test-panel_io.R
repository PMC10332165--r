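test_that("a wide CSV panel round-trips through write and read", {
  panel <- generate_panel(synthetic_config(n_regions = 11, years = 2019,
                                           seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_table(as.data.frame(panel), path, round_digits = NULL)
  back <- read_panel(path)
  expect_equal(nrow(back$observations), 11)
  expect_equal(back$observations$region_id, panel$observations$region_id)
  expect_equal(back$observations$population, panel$observations$population,
               tolerance = 1e-12)

  # already-rounded data survives a second cycle bit-identically
  rounded <- write_table(as.data.frame(panel), path, round_digits = 3)
  again <- write_table(as.data.frame(read_panel(path)), path,
                       round_digits = 3)
  expect_identical(rounded, again)
})

test_that("schema and validation errors carry the offending coordinates", {
  panel <- generate_panel(synthetic_config(n_regions = 4, years = 2019,
                                           seed = 3))
  df <- as.data.frame(panel)

  expect_error(regional_panel(df[, setdiff(names(df), "area")]),
               "area", class = "hrequity_schema_error")

  bad <- df; bad$population[2] <- 0
  expect_error(regional_panel(bad), "population",
               class = "hrequity_validation_error")

  bad <- df; bad$beds[3] <- -1
  err <- tryCatch(regional_panel(bad), error = identity)
  expect_s3_class(err, "hrequity_validation_error")
  expect_match(conditionMessage(err), "beds")
  expect_match(conditionMessage(err), "row 3")

  bad <- df; bad$gdp_per_capita <- as.character(bad$gdp_per_capita)
  bad$gdp_per_capita[1] <- "n/a"
  expect_error(regional_panel(bad), "non-numeric",
               class = "hrequity_validation_error")

  expect_error(regional_panel(rbind(df, df[1, ])),
               class = "hrequity_duplication_error")

  expect_error(regional_panel(df, grouping = c(R01 = "a")),
               "cover", class = "hrequity_validation_error")
})

test_that("long-format input pivots to the wide layout", {
  panel <- generate_panel(synthetic_config(n_regions = 3, years = 2018:2019,
                                           seed = 5))
  wide <- as.data.frame(panel)
  ind <- panel$indicators$id
  long <- do.call(rbind, lapply(ind, function(k) {
    cbind(wide[, c("region_id", "region_name", "year", "population", "area",
                   "gdp_per_capita")],
          indicator = k, value = wide[[k]])
  }))
  back <- pivot_panel_wide(long)
  expect_equal(back[order(back$region_id, back$year), c(names(wide))],
               wide[order(wide$region_id, wide$year), ],
               ignore_attr = TRUE)
})

test_that("reach aggregation sums extensives and population-weights GDP", {
  panel <- toy_panel(population = c(10, 30), area = c(5, 5), gdp = c(2, 4),
                     values = list(x = c(7, 13)),
                     grouping = c(r1 = "g", r2 = "g"))
  agg <- aggregate_reaches(panel)
  obs <- agg$observations
  expect_equal(obs$population, 40)
  expect_equal(obs$area, 10)
  expect_equal(obs$x, 20)
  expect_equal(obs$gdp_per_capita, (10 * 2 + 30 * 4) / 40)  # 3.5

  expect_error(aggregate_reaches(toy_panel(1, 1, 1, list(x = 1))),
               "grouping", class = "hrequity_validation_error")
})

test_that("aggregation conserves totals and ignores province row order", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(6:12, 1)
    groups <- sort(sample(paste0("g", 1:3), n, replace = TRUE))
    df <- as.data.frame(random_panel(n))
    panel <- regional_panel(df, grouping = stats::setNames(groups,
                                                           df$region_id),
                            indicators = indicator_schema("x"))
    agg <- aggregate_reaches(panel)
    expect_equal(sum(agg$observations$population), sum(df$population),
                 tolerance = 1e-9)
    expect_equal(sum(agg$observations$area), sum(df$area), tolerance = 1e-9)
    expect_equal(sum(agg$observations$x), sum(df$x), tolerance = 1e-9)

    perm <- sample(n)
    panel2 <- regional_panel(df[perm, ],
                             grouping = stats::setNames(groups, df$region_id),
                             indicators = indicator_schema("x"))
    agg2 <- aggregate_reaches(panel2)
    o1 <- agg$observations[order(agg$observations$region_id), ]
    o2 <- agg2$observations[order(agg2$observations$region_id), ]
    expect_equal(o1$population, o2$population, tolerance = 1e-12)
    expect_equal(o1$x, o2$x, tolerance = 1e-12)
    expect_equal(o1$gdp_per_capita, o2$gdp_per_capita, tolerance = 1e-12)
  }
})

test_that("explicit parent totals override column sums", {
  panel <- toy_panel(population = c(10, 10), area = c(10, 10), gdp = c(1, 2),
                     values = list(x = c(5, 5)))
  panel$parent_totals <- data.frame(year = 2019, population = 100, area = 100,
                                    x = 100)
  hrad <- compute_hrad(panel, "x", 2019)
  # each region holds 5% of the explicit parent resource on 10% of its area
  expect_equal(unname(hrad), c(0.5, 0.5))
})

test_that("table writing rounds half away from zero and supports JSON", {
  expect_equal(round_half_away(0.356156, 3), 0.356)
  expect_equal(round_half_away(0.5, 0), 1)
  expect_equal(round_half_away(-0.5, 0), -1)
  expect_equal(round_half_away(2.6745, 3), 2.675)  # stored just below the half
  expect_equal(round_half_away(0.0005, 3), 0.001)

  tab <- data.frame(region_id = "a", value = 0.356156)
  path <- withr::local_tempfile(fileext = ".csv")
  write_table(tab, path, round_digits = 3)
  expect_match(readLines(path)[2], "0.356", fixed = TRUE)

  jpath <- withr::local_tempfile(fileext = ".json")
  write_table(tab, jpath, round_digits = 3, format = "json")
  parsed <- jsonlite::read_json(jpath)
  expect_type(parsed[[1]]$value, "double")
  expect_equal(parsed[[1]]$value, 0.356)

  expect_error(write_table(tab, file.path(tempdir(), "no", "such", "..",
                                          rep(paste(rep("x", 300),
                                                    collapse = ""), 1))),
               class = "hrequity_io_error")
})
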