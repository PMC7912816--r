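#' Define a simulation scenario
#'
#' A scenario fixes everything the harvest-data generator needs: the true
#' causal model, one coefficient per edge (on the linear-predictor scale of
#' the child), per-vertex intercepts and noise scales, the survey design,
#' and the random seed. Coefficients apply to the parent on its analysis
#' transform scale (log grams for weights, days for \code{HD}, class index
#' for depth); the child is drawn from its declared family (Gaussian on the
#' log scale for weights, shifted Poisson for the depth class, truncated
#' Poisson for the shape index, Gamma with log link for the combined weight
#' of the remaining cluster members, logistic-mean Gaussian clipped to
#' [0, 1] for maturity).
#'
#' @param truth A \code{"causal_model"} over the single-fruitbody variables
#'   (\code{HD}, \code{depth}, \code{weight}, \code{shape},
#'   \code{maturity}) or the cluster variables (\code{HD}, \code{depth},
#'   \code{we_largest}, \code{we_rest}, \code{shape}).
#' @param coefficients Named numeric vector, one entry per edge, named
#'   \code{"parent->child"}.
#' @param intercepts Named numeric vector by vertex (linear-predictor
#'   scale: log grams, log lambda, logit maturity). Missing vertices take
#'   the package defaults.
#' @param noise Named numeric vector by vertex: Gaussian standard
#'   deviations for weights/maturity and the Gamma shape parameter for
#'   \code{we_rest}.
#' @param n_digs Number of digs to generate.
#' @param cluster_fraction Fraction of digs that are clusters; defaults to
#'   1 for a cluster-variable truth and 0 otherwise.
#' @param surveys_per_season Number of surveys per fruiting season
#'   (default 7, November to March).
#' @param seasons Character vector of season labels (default two
#'   consecutive seasons).
#' @param typology Typology labels the digs are spread over uniformly.
#' @param size_noise_sd Standard deviation of the multiplicative
#'   (log-scale) noise in the weight-volume relation used to derive the
#'   caliper diameters; 0 makes weight an exact ellipsoid function of the
#'   diameters.
#' @param seed Integer seed; the same scenario always yields the same
#'   dataset.
#' @return A \code{"simulation_scenario"}.
#' @export
simulation_scenario <- function(truth, coefficients = NULL, intercepts = NULL,
                                noise = NULL, n_digs = 200,
                                cluster_fraction = NULL,
                                surveys_per_season = 7,
                                seasons = c("2016-2017", "2017-2018"),
                                typology = typology_levels(),
                                size_noise_sd = 0.05, seed = 1L) {
  stopifnot(inherits(truth, "causal_model"))
  is_cluster <- "we_largest" %in% truth$vertices
  if (is.null(cluster_fraction))
    cluster_fraction <- if (is_cluster) 1 else 0
  stopifnot(cluster_fraction >= 0, cluster_fraction <= 1, n_digs >= 1)
  edge_names <- if (nrow(truth$edges))
    paste0(truth$edges[, 1], "->", truth$edges[, 2]) else character(0)
  cf <- stats::setNames(rep(0, length(edge_names)), edge_names)
  if (!is.null(coefficients)) {
    bad <- setdiff(names(coefficients), edge_names)
    if (length(bad))
      stop("coefficient(s) for edges not in the model: ",
           paste(bad, collapse = ", "))
    cf[names(coefficients)] <- coefficients
  }
  missing_cf <- setdiff(edge_names, names(coefficients))
  if (!is.null(coefficients) && length(missing_cf))
    stop("every edge needs a coefficient; missing: ",
         paste(missing_cf, collapse = ", "))

  ic <- default_intercepts()
  if (!is.null(intercepts)) ic[names(intercepts)] <- intercepts
  ns <- default_noise()
  if (!is.null(noise)) ns[names(noise)] <- noise

  structure(list(truth = truth, coefficients = cf, intercepts = ic,
                 noise = ns, n_digs = n_digs,
                 cluster_fraction = cluster_fraction,
                 surveys_per_season = surveys_per_season, seasons = seasons,
                 typology = typology, size_noise_sd = size_noise_sd,
                 seed = as.integer(seed)),
            class = "simulation_scenario")
}

# baseline marginal parameters (linear-predictor scale); plausible ranges
# for an irrigated truffle orchard, documented as assumptions
default_intercepts <- function() {
  c(HD = 0,                      # HD is drawn from the survey grid
    depth = log(0.8),            # mean depth class ~ 1.8 (mostly 0-20 cm)
    weight = log(20),            # median single fruitbody ~ 20 g
    we_largest = log(18),
    we_rest = log(15),
    shape = log(4.5),            # shape index centered mid-scale
    maturity = -1.3)             # logit: early-season fruitbodies immature
}

default_noise <- function() {
  c(weight = 0.85,               # sd of log weight
    we_largest = 0.75,
    we_rest = 1.6,               # gamma shape parameter
    maturity = 0.25)             # sd around the logistic mean
}

#' Built-in simulation scenarios
#'
#' Named presets covering the pipeline's study conditions. Effect signs
#' follow the field pattern: harvesting date negatively related to weight
#' and strongly positively to spore maturity, weight strongly negatively
#' related to the shape index, and (in clusters) the combined weight of the
#' remaining fruitbodies strongly positively related to the weight of the
#' largest one. Magnitudes are set so the generating path explains a few
#' percent (harvesting-date effects) to 20-35 percent (weight-shape,
#' maturity, within-cluster weights) of the response variability, the range
#' seen in orchard harvest data. Sample sizes default to the survey scale
#' (604 single-fruitbody digs, 308 cluster digs, 1047 fruitbodies for the
#' diameter-weight recipe).
#'
#' @return Named list of \code{"simulation_scenario"} objects:
#'   \code{single_modelA_like}, \code{single_modelB_like},
#'   \code{cluster_modelD_like}, \code{null_all_independent},
#'   \code{pls_geometry}.
#' @export
preset_scenarios <- function() {
  mods <- truffle_models()
  single_null <- causal_model("single_null", mods$single_A$vertices,
                              family = mods$single_A$family,
                              transform = c(weight = "log"))
  # the shape intercept offsets the negative weight effect at the median
  # weight so the generated index stays centered mid-scale
  shape_centered <- c(shape = log(4.5) + 0.25 * log(20))
  list(
    single_modelA_like = simulation_scenario(
      mods$single_A,
      coefficients = c("HD->weight" = -0.0042,
                       "HD->maturity" = 0.024,
                       "weight->shape" = -0.25),
      intercepts = shape_centered,
      n_digs = 604, seed = 101L),
    single_modelB_like = simulation_scenario(
      mods$single_B,
      coefficients = c("HD->weight" = -0.0042,
                       "HD->maturity" = 0.024,
                       "weight->shape" = -0.25,
                       "depth->weight" = 0.12,
                       "depth->maturity" = 0.18,
                       "weight->maturity" = -0.06),
      intercepts = shape_centered,
      n_digs = 604, seed = 102L),
    cluster_modelD_like = simulation_scenario(
      mods$cluster_D,
      coefficients = c("HD->we_largest" = -0.0015,
                       "HD->we_rest" = -0.004,
                       "we_largest->shape" = -0.25,
                       "we_rest->we_largest" = 0.45,
                       "we_rest->shape" = 0.06),
      intercepts = c(shape = log(4.5) + 0.25 * log(18) - 0.06 * log(15)),
      n_digs = 308, seed = 103L),
    null_all_independent = simulation_scenario(
      single_null, n_digs = 604, seed = 104L),
    pls_geometry = simulation_scenario(
      mods$single_A,
      coefficients = c("HD->weight" = -0.0042,
                       "HD->maturity" = 0.024,
                       "weight->shape" = -0.25),
      intercepts = shape_centered,
      n_digs = 1047, size_noise_sd = 0.10, seed = 105L))
}

survey_days <- function(surveys_per_season) {
  # evenly spaced surveys over the November-March window (~20 weeks)
  round(seq(0, 140, length.out = surveys_per_season))
}

# truncated poisson on 1..9 by redrawing out-of-range values
draw_shape <- function(lambda, warn = TRUE) {
  n <- length(lambda)
  out <- rep(NA_integer_, n)
  todo <- seq_len(n)
  draws_total <- 0; kept <- 0
  for (iter in 1:50) {
    if (!length(todo)) break
    d <- stats::rpois(length(todo), lambda[todo])
    draws_total <- draws_total + length(todo)
    ok <- d >= 1 & d <= 9
    out[todo[ok]] <- d[ok]
    kept <- kept + sum(ok)
    todo <- todo[!ok]
  }
  if (length(todo)) out[todo] <- pmin(9L, pmax(1L, stats::rpois(length(todo),
                                                                lambda[todo])))
  if (warn && draws_total >= 20 && (draws_total - kept) / draws_total > 0.2)
    warning(sprintf("shape-index truncation discarded %.0f%% of draws",
                    100 * (draws_total - kept) / draws_total))
  out
}

# ellipsoid diameters (mm) from fresh weight (g); the middle axis is the
# mean of the other two, density ~1.05 g/cm3; multiplicative log-scale
# noise enters through the volume
diameters_from_weight <- function(weight_g, size_noise_sd) {
  n <- length(weight_g)
  vol <- weight_g / 1.05
  if (size_noise_sd > 0) vol <- vol * exp(stats::rnorm(n, 0, size_noise_sd))
  aspect <- 1 + abs(stats::rnorm(n, 0, 0.12))
  d0 <- (12 * vol / (pi * (aspect + 1 / aspect)))^(1 / 3) * 10
  cbind(dmax_mm = d0 * aspect, dmin_mm = d0 / aspect)
}

linear_predictor <- function(scenario, vertex, values, n) {
  lp <- rep(scenario$intercepts[[vertex]], n)
  pa <- parents(scenario$truth, vertex)
  for (p in pa) {
    cf <- scenario$coefficients[[paste0(p, "->", vertex)]]
    pv <- values[[p]]
    if (scenario$truth$transform[[p]] == "log") pv <- log(pv)
    lp <- lp + cf * pv
  }
  lp
}

draw_vertex <- function(scenario, vertex, values, n) {
  lp <- linear_predictor(scenario, vertex, values, n)
  ns <- scenario$noise
  switch(vertex,
    HD = values$HD,                         # drawn from the survey grid
    depth = 1L + stats::rpois(n, exp(lp)),
    weight = exp(lp + stats::rnorm(n, 0, ns[["weight"]])),
    we_largest = exp(lp + stats::rnorm(n, 0, ns[["we_largest"]])),
    we_rest = stats::rgamma(n, shape = ns[["we_rest"]],
                            rate = ns[["we_rest"]] / exp(lp)),
    shape = draw_shape(exp(lp)),
    maturity = pmin(1, pmax(0, stats::plogis(lp) +
                              stats::rnorm(n, 0, ns[["maturity"]]))),
    stop("no generator for vertex ", vertex))
}

# split the combined weight of the remaining members into m-1 positive
# parts, each below the largest member's weight
split_we_rest <- function(we_rest, we_largest) {
  m_rest <- 1L + stats::rgeom(1, 0.6)            # >= 1 remaining member
  m_rest <- max(m_rest, ceiling(we_rest / (0.95 * we_largest)))
  if (m_rest == 1) {
    if (we_rest < we_largest) return(we_rest)
    m_rest <- 2L
  }
  for (try in 1:25) {
    g <- stats::rgamma(m_rest, shape = 3)
    parts <- we_rest * g / sum(g)
    if (max(parts) < we_largest) return(parts)
  }
  rep(we_rest / m_rest, m_rest)                 # feasible by construction
}

#' Generate a synthetic harvest dataset
#'
#' Ancestral sampling from the scenario's true causal model in topological
#' order, then assembly into the harvest-record schema: survey dates on the
#' seasonal grid, dig identifiers, per-fruitbody caliper diameters derived
#' from weight through an ellipsoid volume relation, and (for cluster digs)
#' the combined remaining weight decomposed into individual members. With a
#' single-fruitbody truth any cluster digs are filled with independent
#' baseline marginals, and vice versa. A fixed seed yields a bit-identical
#' dataset.
#'
#' @param scenario A \code{"simulation_scenario"}.
#' @param seed Optional seed overriding the scenario's.
#' @return A harvest data frame (see \code{\link{read_harvest}} for the
#'   schema) that satisfies all record invariants.
#' @examples
#' x <- simulate_harvest(preset_scenarios()$single_modelA_like, seed = 42)
#' head(x)
#' @export
simulate_harvest <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  set.seed(if (is.null(seed)) scenario$seed else as.integer(seed))
  n <- scenario$n_digs
  truth <- scenario$truth
  is_cluster_truth <- "we_largest" %in% truth$vertices

  season <- sample(scenario$seasons, n, replace = TRUE)
  block <- sample(paste0("B", 1:3), n, replace = TRUE)
  typology <- sample(scenario$typology, n, replace = TRUE)
  grid <- survey_days(scenario$surveys_per_season)
  HD <- sample(grid, n, replace = TRUE)
  n_clusters <- round(scenario$cluster_fraction * n)
  is_cluster <- rep(FALSE, n)
  if (n_clusters > 0) is_cluster[sample.int(n, n_clusters)] <- TRUE

  values <- list(HD = HD)
  for (v in topological_order(truth))
    values[[v]] <- draw_vertex(scenario, v, values, n)
  # digs of the other type fall back to independent baseline marginals
  base <- scenario
  if (is_cluster_truth) {
    base$truth <- causal_model("baseline",
                               c("HD", "depth", "weight", "shape",
                                 "maturity"),
                               family = truffle_models()$single_A$family,
                               transform = c(weight = "log"))
    for (v in c("weight", "shape")) if (is.null(values[[v]]))
      values[[v]] <- draw_vertex(base, v, values, n)
    values$maturity <- rep(NA_real_, n)
  } else {
    base$truth <- causal_model("baseline",
                               c("HD", "depth", "we_largest", "we_rest",
                                 "shape"),
                               family = truffle_models()$cluster_A$family,
                               transform = c(we_largest = "log",
                                             we_rest = "log"))
    for (v in c("we_largest", "we_rest")) if (is.null(values[[v]]))
      values[[v]] <- draw_vertex(base, v, values, n)
  }

  start <- season_start_date(season)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    dig_id <- sprintf("D%05d", i)
    common <- list(season = season[i], block = block[i],
                   typology = typology[i], dig_id = dig_id,
                   harvest_date = as.character(start[i] + HD[i]),
                   depth_class = values$depth[i])
    if (!is_cluster[i]) {
      rows[[i]] <- data.frame(common, dig_type = "single",
                              weight_g = values$weight[i],
                              shape_index = values$shape[i],
                              maturity = if (is_cluster_truth) NA_real_ else
                                values$maturity[i],
                              role = "single", stringsAsFactors = FALSE)
    } else {
      wl <- values$we_largest[i]
      parts <- split_we_rest(values$we_rest[i], wl)
      shp_rest <- draw_shape(rep(exp(default_intercepts()[["shape"]]),
                                 length(parts)), warn = FALSE)
      rows[[i]] <- data.frame(
        common, dig_type = "cluster",
        weight_g = c(wl, parts),
        shape_index = c(values$shape[i], shp_rest),
        maturity = NA_real_,
        role = c("largest", rep("other", length(parts))),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  dm <- diameters_from_weight(out$weight_g, scenario$size_noise_sd)
  out$dmax_mm <- dm[, "dmax_mm"]
  out$dmin_mm <- dm[, "dmin_mm"]
  out <- out[, harvest_columns()]
  rownames(out) <- NULL
  out
}

#' Simulate linear-Gaussian data from a causal model
#'
#' Plain ancestral sampling with standard-normal exogenous noise: every
#' vertex is its parents' weighted sum plus Gaussian noise. This is the
#' reference generator for calibration studies of the claim tests and
#' Fisher's C, where the linear-Gaussian assumptions of the
#' partial-correlation engine hold exactly.
#'
#' @param model A \code{"causal_model"} (families/transforms are ignored).
#' @param n Sample size.
#' @param coefficients Named vector \code{"parent->child"}; edges not named
#'   default to \code{coef_default}.
#' @param coef_default Coefficient for unnamed edges (default 0.5).
#' @param sd Noise standard deviation (per vertex).
#' @return Data frame with one numeric column per vertex.
#' @export
simulate_gaussian_dag <- function(model, n, coefficients = NULL,
                                  coef_default = 0.5, sd = 1) {
  out <- list()
  for (v in topological_order(model)) {
    x <- stats::rnorm(n, 0, sd)
    for (p in parents(model, v)) {
      cf <- coefficients[[paste0(p, "->", v)]]
      if (is.null(cf) || is.na(cf)) cf <- coef_default
      x <- x + cf * out[[p]]
    }
    out[[v]] <- x
  }
  as.data.frame(out)[model$vertices]
}

#' @export
print.simulation_scenario <- function(x, ...) {
  cat("Simulation scenario: truth '", x$truth$name, "', ", x$n_digs,
      " digs (", round(100 * x$cluster_fraction), "% clusters), seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}
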