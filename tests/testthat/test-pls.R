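# ellipsoid-volume fixture: weight (g) derived from caliper diameters (mm)
# with the middle axis the mean of the other two and density 1.05 g/cm3
ellipsoid_fixture <- function(n, noise_sd = 0, seed = 1) {
  set.seed(seed)
  aspect <- 1 + abs(rnorm(n, 0, 0.15))
  d0 <- exp(rnorm(n, log(38), 0.30))
  dmax <- d0 * aspect
  dmin <- d0 / aspect
  w <- 1.05 * (pi / 6) * (dmax / 10) * (dmin / 10) * ((dmax + dmin) / 20)
  if (noise_sd > 0) w <- w * exp(rnorm(n, 0, noise_sd))
  data.frame(dmax_mm = dmax, dmin_mm = dmin, weight_g = w)
}

test_that("one component on one feature reproduces the least-squares fit", {
  d <- ellipsoid_fixture(150)
  X <- matrix(d$dmax_mm, ncol = 1, dimnames = list(NULL, "dmax"))
  fit <- fit_pls(X = X, y = d$weight_g, n_components = 1)
  pls_pred <- predict(fit, X)
  ols_pred <- fitted(lm(weight_g ~ dmax_mm, d))
  expect_lt(max(abs(pls_pred - ols_pred)), 1e-8)
})

test_that("seven components recover a noiseless ellipsoid weight exactly", {
  d <- ellipsoid_fixture(400)
  fit <- fit_pls(d, n_components = 7)
  expect_gte(fit$explained[7], 0.99)
  val <- suppressWarnings(validate_pls(fit, d))  # lm warns on a perfect fit
  expect_equal(val$r_squared, 1, tolerance = 1e-6)
  expect_equal(val$slope, 1, tolerance = 1e-3)
})

test_that("variance explained is non-decreasing in the component count", {
  d <- ellipsoid_fixture(300, noise_sd = 0.15)
  fit <- fit_pls(d, n_components = 7)
  expect_true(all(diff(fit$explained) >= -1e-10))
})

test_that("duplicate feature columns leave predictions unchanged", {
  # at the full rank of the feature span PLS coincides with least squares,
  # so a duplicated column cannot move the predictions
  d <- ellipsoid_fixture(200, noise_sd = 0.1)
  X <- pls_features(d$dmax_mm, d$dmin_mm)
  fit <- fit_pls(X = X, y = d$weight_g, n_components = 7)
  Xd <- cbind(X, dmax_copy = X[, "dmax"])
  fitd <- fit_pls(X = Xd, y = d$weight_g, n_components = 7)
  expect_equal(unname(predict(fitd, Xd)), unname(predict(fit, X)),
               tolerance = 1e-6)
})

test_that("predictions agree with an established PLS implementation", {
  skip_if_not_installed("mixOmics")
  d <- ellipsoid_fixture(250, noise_sd = 0.1)
  X <- pls_features(d$dmax_mm, d$dmin_mm)
  for (nc in c(2, 4, 7)) {
    mine <- predict(fit_pls(X = X, y = d$weight_g, n_components = nc), X)
    ref <- mixOmics::pls(X, matrix(d$weight_g, ncol = 1,
                                   dimnames = list(NULL, "w")),
                         ncomp = nc, mode = "regression", scale = TRUE)
    ref_pred <- predict(ref, X)$predict[, , nc]
    expect_equal(unname(mine), unname(ref_pred), tolerance = 1e-6)
  }
})

test_that("rank-deficient feature sets are rejected with advice", {
  d <- ellipsoid_fixture(100)
  X <- cbind(a = d$dmax_mm, b = 2 * d$dmax_mm + 1, c = d$dmin_mm)
  expect_error(fit_pls(X = X, y = d$weight_g, n_components = 3),
               "fewer components")
})

test_that("validation regresses log observed on log predicted", {
  d <- ellipsoid_fixture(200, noise_sd = 0.1)
  fit <- fit_pls(d, n_components = 7)
  perfect <- data.frame(d, check.names = FALSE)
  perfect$weight_g <- predict(fit, d)   # observations equal to predictions
  val <- suppressWarnings(validate_pls(fit, perfect))
  expect_equal(val$r_squared, 1, tolerance = 1e-10)
  expect_equal(val$slope, 1, tolerance = 1e-10)

  set.seed(99)
  noise <- d
  noise$weight_g <- sample(noise$weight_g)   # predictions uninformative
  val2 <- validate_pls(fit, noise)
  expect_lt(val2$r_squared, 0.05)
})

test_that("a fitted model survives JSON serialization", {
  d <- ellipsoid_fixture(150, noise_sd = 0.05)
  fit <- fit_pls(d, n_components = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_pls(fit, path)
  fit2 <- read_pls(path)
  expect_equal(predict(fit2, d), predict(fit, d), tolerance = 1e-8)
})
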