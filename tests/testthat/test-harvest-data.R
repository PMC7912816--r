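test_that("CSV round-trip preserves a generated dataset", {
  x <- simulate_harvest(preset_scenarios()$single_modelA_like, seed = 7)
  x <- x[1:50, ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_harvest(x, path)
  y <- read_harvest(path)
  expect_equal(y$weight_g, x$weight_g, tolerance = 1e-12)
  expect_identical(y$dig_id, x$dig_id)
  expect_identical(y$shape_index, as.integer(x$shape_index))
  expect_equal(y$maturity, x$maturity, tolerance = 1e-12)
  expect_identical(y$harvest_date, x$harvest_date)
  # and a second round-trip is byte-stable
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_harvest(y, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("schema violations are reported with their rows", {
  x <- make_records(c(10, 20, 30))
  x$shape_index[2] <- 10
  expect_match(validate_harvest(x), "row 2.*shape_index", all = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_harvest(x, path)
  expect_error(read_harvest(path), "row 2")

  x2 <- make_records(c(10, -1))
  expect_match(validate_harvest(x2), "row 2.*weight", all = FALSE)

  x3 <- make_records(10)
  x3$weight_g <- "heavy"
  write_harvest(x3, path)
  expect_error(read_harvest(path), "non-numeric.*weight_g")

  x4 <- make_records(10)[, -3]   # drop typology
  write_harvest(x4, path)
  expect_error(read_harvest(path), "missing mandatory column")
})

test_that("cluster dig invariants are enforced", {
  lone <- make_records(10, dig_type = "cluster", dig_id = "C1",
                       role = "largest")
  expect_match(validate_harvest(lone), ">= 2 records", all = FALSE)
  bad_largest <- make_records(c(5, 9), dig_type = "cluster",
                              role = c("largest", "other"))
  expect_match(validate_harvest(bad_largest), "maximal weight", all = FALSE)
})

test_that("harvest day is a calendar offset from the season start", {
  expect_identical(harvest_day("2016-11-01", "2016-11-01"), 0L)
  expect_identical(harvest_day("2016-11-08", "2016-11-01"), 7L)
  # monotone across the year boundary
  expect_identical(harvest_day(c("2016-12-30", "2017-01-06"), "2016-11-01"),
                   c(59L, 66L))
  expect_error(harvest_day("2016-10-20", "2016-11-01"), "before season_start")
  expect_identical(season_start_date("2016-2017"), as.Date("2016-11-01"))
  expect_identical(harvest_day("2017-01-06", season = "2016-2017"), 66L)
})

test_that("maturity index is the mature-asci proportion with a sampling floor", {
  expect_identical(maturity_index(25, 50), 0.5)
  expect_identical(maturity_index(0, 60), 0)
  expect_identical(maturity_index(60, 60), 1)
  expect_warning(maturity_index(10, 40), "undersampled")
  expect_error(maturity_index(10, 40, strict = TRUE), "undersampled")
  expect_error(maturity_index(70, 60), "0..n_total")
})

test_that("cluster aggregation selects the largest and conserves mass", {
  x <- make_records(c(30, 10, 5), dig_type = "cluster")
  agg <- aggregate_clusters(x)
  expect_equal(agg$we_largest_g, 30)
  expect_equal(agg$we_rest_g, 15)

  tie <- make_records(c(8, 8), dig_type = "cluster",
                      role = c("largest", "other"), shape_index = c(3, 7))
  agg_tie <- aggregate_clusters(tie)
  expect_equal(agg_tie$we_largest_g, 8)
  expect_equal(agg_tie$we_rest_g, 8)
  expect_equal(agg_tie$shape_largest, 3)   # first record wins the tie

  mixed <- rbind(make_records(c(12, 20)),
                 make_records(c(30, 10, 5), dig_type = "cluster"))
  expect_identical(nrow(aggregate_clusters(mixed)), 1L)

  # mass conservation on a generated dataset
  sim <- simulate_harvest(preset_scenarios()$cluster_modelD_like, seed = 3)
  agg_sim <- aggregate_clusters(sim)
  totals <- tapply(sim$weight_g[sim$dig_type == "cluster"],
                   sim$dig_id[sim$dig_type == "cluster"], sum)
  expect_equal(agg_sim$we_largest_g + agg_sim$we_rest_g,
               as.vector(totals[agg_sim$dig_id]), tolerance = 1e-10)
})

test_that("typology subsets partition the dataset", {
  x <- simulate_harvest(preset_scenarios()$single_modelA_like, seed = 11)
  tab <- analysis_table(x, "single")
  sizes <- vapply(c("substrate", "BS1", "BS2", "BS3"), function(ty)
    nrow(analysis_table(x, "single", typology = ty)), numeric(1))
  expect_equal(sum(sizes), nrow(tab))
})
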