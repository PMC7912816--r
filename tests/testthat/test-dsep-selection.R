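test_that("Fisher's C combines claim probabilities as -2 sum log p", {
  expect_equal(fishers_c(c(1, 1, 1))$C, 0)
  expect_equal(fishers_c(c(1, 1, 1))$p_value, 1)
  fc <- fishers_c(0.5)
  expect_equal(fc$C, -2 * log(0.5), tolerance = 1e-12)
  expect_identical(fc$df, 2L)
  expect_error(fishers_c(numeric(0)), "empty")
  expect_warning(fc0 <- fishers_c(c(0.5, 0)), "floored")
  expect_lt(fc0$p_value, 1e-100)
  # monotone non-increasing in each claim p-value
  expect_gt(fishers_c(c(0.2, 0.5))$C, fishers_c(c(0.3, 0.5))$C)
})

test_that("chi-square tails reproduce the published model-test probabilities", {
  expect_equal(round(fishers_c_tail(22.3, 14), 2), 0.07)
  expect_equal(round(fishers_c_tail(2.6, 6), 2), 0.86)
  expect_equal(round(fishers_c_tail(12.7, 10), 2), 0.24)
})

test_that("AICc applies the small-sample correction", {
  expect_equal(aicc(0, 0, 100), 0)
  # n -> Inf limit: C + 2K
  expect_equal(aicc(10, 3, 1e9), 10 + 6, tolerance = 1e-6)
  expect_error(aicc(10, 9, 10), "undefined")
  # equal K and n: ordering by C
  a <- aicc(c(5, 7, 9), 3, 50)
  expect_identical(order(a), order(c(5, 7, 9)))
})

test_that("Akaike weights reproduce the published model-weight columns", {
  # singles, substrate: models A, B, C
  expect_equal(round(akaike_weights(c(36.9, 40.7, 41.4)), 2),
               c(0.80, 0.12, 0.08))
  # singles, bulk soil of block 2 (entries robust to the 1-dp AICc rounding)
  expect_equal(round(akaike_weights(c(31.0, 35.6, 35.7))[2:3], 2),
               c(0.08, 0.08))
  # clusters, substrate: only D and E consistent
  expect_equal(round(akaike_weights(c(35.2, 38.6)), 2), c(0.85, 0.15))
  # clusters, bulk soil of block 1: A, B, D, E enter the weighting
  expect_equal(round(akaike_weights(c(43.6, 46.1, 39.7, 45.8))[2:4], 2),
               c(0.03, 0.81, 0.04))
})

test_that("weights are normalized and shift-invariant", {
  w <- akaike_weights(c(10, 12, 15))
  expect_equal(sum(w), 1, tolerance = 1e-9)
  expect_equal(w, akaike_weights(c(10, 12, 15) + 37.5), tolerance = 1e-12)
  expect_equal(akaike_weights(c(5, 5, 5)), rep(1 / 3, 3))
  expect_equal(akaike_weights(42), 1)
})

test_that("model comparison excludes rejected models and flags empty sets", {
  mk <- function(model, C, df, p, K, n = 100)
    structure(list(model = model, C = C, df = df, p_value = p, n = n,
                   K = K, AICc = if (p > 0.05) aicc(C, K, n) else NA_real_,
                   consistent = p > 0.05, alpha = 0.05),
              class = "dsep_result")
  cmp <- compare_models(list(mk("A", 74.9, 14, 1e-4, NA),
                             mk("D", 6.6, 10, 0.76, 13.3),
                             mk("E", 2.6, 6, 0.86, 16.4)))
  expect_identical(cmp$included, c(FALSE, TRUE, TRUE))
  expect_true(is.na(cmp$weight[1]))
  expect_equal(sum(cmp$weight, na.rm = TRUE), 1, tolerance = 1e-9)
  expect_equal(min(cmp$delta_AICc, na.rm = TRUE), 0)
  expect_identical(best_model(cmp), "D")
  fmt <- format_comparison(cmp)
  expect_identical(unname(fmt[1, "W"]), "-")
  expect_identical(unname(fmt[1, "K"]), "-")

  none <- compare_models(list(mk("A", 74.9, 14, 1e-4, NA)))
  expect_true(all(is.na(none$weight)))
  expect_match(attr(none, "note"), "no model")
  expect_identical(best_model(none), NA_character_)
})

test_that("parameter counting sums coefficients and effective df", {
  m <- causal_model("two_parents", c("a", "b", "y"),
                    list(c("a", "y"), c("b", "y")))
  set.seed(6)
  d <- simulate_gaussian_dag(m, 200)
  sfit <- fit_structural_equations(m, d, smooth = FALSE)
  expect_equal(count_parameters(sfit), 3)              # intercept + 2 slopes
  expect_equal(count_parameters(sfit, count_parentless = TRUE), 5)
  ssm <- fit_structural_equations(m, d, smooth = TRUE)
  K <- count_parameters(ssm)
  expect_gte(K, 3)                                     # edf >= 1 per smooth
  expect_lte(K, 1 + 2 * 3)                             # k = 4 caps edf at 3
})
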