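test_that("noiseless linear gaussian data are interpolated exactly", {
  m <- causal_model("line", c("x", "y"), list(c("x", "y")))
  d <- data.frame(x = seq(-2, 2, length.out = 60))
  d$y <- 1.5 - 2 * d$x
  # REML may report a step failure on an exactly deterministic response
  sfit <- suppressWarnings(fit_structural_equations(m, d, smooth = TRUE))
  expect_lt(max(abs(fitted(sfit$fits$y) - d$y)), 1e-6)
  rep <- path_report(sfit)
  expect_identical(rep$direction, "negative")
})

test_that("D2 of a single linear gaussian predictor equals the OLS R2", {
  set.seed(8)
  n <- 500
  d <- data.frame(x = rnorm(n))
  d$y <- 0.7 * d$x + rnorm(n)
  m <- causal_model("line", c("x", "y"), list(c("x", "y")))
  sfit <- fit_structural_equations(m, d, smooth = FALSE)
  r2 <- summary(lm(y ~ x, d))$r.squared
  expect_equal(deviance_explained(sfit, "y", "x") / 100, r2,
               tolerance = 1e-6)
})

test_that("D2 tracks the generating signal fraction and saturates at 100", {
  set.seed(9)
  n <- 2000
  x <- rnorm(n)
  # R2 = 0.3: signal sd b with b^2/(b^2+1) = 0.3
  b <- sqrt(0.3 / 0.7)
  d <- data.frame(x = x, y = b * x + rnorm(n))
  m <- causal_model("line", c("x", "y"), list(c("x", "y")))
  sfit <- fit_structural_equations(m, d, smooth = TRUE)
  expect_lt(abs(deviance_explained(sfit, "y", "x") - 30), 3)

  d2 <- data.frame(x = x, y = 2 * x)
  sat <- suppressWarnings(fit_structural_equations(m, d2, smooth = FALSE))
  expect_equal(deviance_explained(sat, "y", "x"), 100, tolerance = 1e-6)

  # a null predictor explains essentially nothing
  m2 <- causal_model("two", c("x", "z", "y"),
                     list(c("x", "y"), c("z", "y")))
  d3 <- data.frame(x = x, z = rnorm(n), y = b * x + rnorm(n))
  s3 <- fit_structural_equations(m2, d3, smooth = TRUE)
  expect_lt(deviance_explained(s3, "y", "z"), 1)
})

test_that("drop-term refits with frozen penalties never reduce the deviance", {
  set.seed(10)
  for (i in 1:12) {
    n <- 250
    d <- data.frame(a = rnorm(n), b = rnorm(n))
    d$y <- 0.5 * d$a + 0.3 * sin(2 * d$b) + rnorm(n)
    m <- causal_model("ab", c("a", "b", "y"),
                      list(c("a", "y"), c("b", "y")))
    sfit <- fit_structural_equations(m, d, smooth = TRUE)
    expect_gte(deviance_explained(sfit, "y", "a"), 0)
    expect_gte(deviance_explained(sfit, "y", "b"), 0)
  }
})

test_that("fitted relationship signs are recovered on synthetic harvests", {
  sim <- simulate_harvest(preset_scenarios()$single_modelA_like, seed = 21)
  tab <- analysis_table(sim, "single")
  sfit <- fit_structural_equations(truffle_models()$single_A, tab)
  rep <- path_report(sfit)
  dir_of <- function(resp, pred)
    rep$direction[rep$response == resp & rep$predictor == pred]
  expect_identical(dir_of("shape", "weight"), "negative")
  expect_identical(dir_of("maturity", "HD"), "positive")
})

test_that("overdispersed poisson responses trigger a warning", {
  set.seed(11)
  n <- 400
  d <- data.frame(x = rnorm(n))
  mu <- exp(1 + 0.2 * d$x)
  d$y <- rnbinom(n, mu = mu, size = 0.6)   # variance far above the mean
  m <- causal_model("od", c("x", "y"), list(c("x", "y")),
                    family = c(y = "poisson"))
  expect_warning(fit_structural_equations(m, d, smooth = FALSE),
                 "overdispersed")
})

test_that("path reports gate D2 on significance", {
  set.seed(12)
  n <- 300
  d <- data.frame(x = rnorm(n), z = rnorm(n))
  d$y <- 0.8 * d$x + rnorm(n)
  m <- causal_model("gate", c("x", "z", "y"),
                    list(c("x", "y"), c("z", "y")))
  sfit <- fit_structural_equations(m, d, smooth = FALSE)
  rep <- path_report(sfit)
  expect_false(is.na(rep$deviance_explained_pct[rep$predictor == "x"]))
  expect_true(is.na(rep$deviance_explained_pct[rep$predictor == "z"]))
  fmt <- format_path_report(rep)
  expect_identical(unname(fmt[fmt[, "Predictor"] == "z", "D2"]), "-")
})
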