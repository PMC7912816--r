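glm_family_for <- function(fam) {
  switch(fam,
         gaussian = stats::gaussian(),
         poisson = stats::poisson(link = "log"),
         gamma = stats::Gamma(link = "log"),
         stop("unknown family: ", fam))
}

# response column on the fitting scale: gaussian responses with a declared
# log transform are fitted on the log scale; poisson/gamma keep the raw
# scale (the log link does the work)
response_values <- function(model, data, vertex) {
  y <- as.numeric(data[[vertex]])
  fam <- model$family[[vertex]]
  if (fam == "gaussian" && model$transform[[vertex]] == "log") {
    if (any(y <= 0, na.rm = TRUE))
      stop("response ", vertex, " must be positive for its log transform")
    y <- log(y)
  }
  if (fam == "gamma" && any(y <= 0, na.rm = TRUE))
    stop("response ", vertex, " must be positive for a gamma family")
  if (fam == "poisson" && any(y < 0, na.rm = TRUE))
    stop("response ", vertex, " must be non-negative for a poisson family")
  y
}

#' Fit the structural equations of a causal model
#'
#' One generalized (additive) regression per child vertex: the response's
#' declared family with identity link for Gaussian (log-weights fitted on
#' the log scale) and log link for Poisson and Gamma; predictors enter on
#' their transform scale, by default through penalized thin-plate smooths
#' so relationships may be non-linear. Poisson equations are checked for
#' overdispersion via the Pearson statistic.
#'
#' @param model A \code{"causal_model"}.
#' @param data Data frame of raw analysis variables.
#' @param smooth Use penalized smooth terms for the predictors
#'   (default) or plain linear terms.
#' @param k Basis dimension of each smooth (default 4).
#' @param method Smoothing-parameter criterion passed to
#'   \code{\link[mgcv]{gam}} (default \code{"REML"}).
#' @param overdispersion_threshold Pearson dispersion ratio above which a
#'   Poisson equation triggers a warning.
#' @return A \code{"structural_fit"}: list with the model, the per-child
#'   \code{\link[mgcv]{gam}} fits, and the fitting options.
#' @export
fit_structural_equations <- function(model, data, smooth = TRUE, k = 4,
                                     method = "REML",
                                     overdispersion_threshold = 1.5) {
  kids <- child_vertices(model)
  if (!length(kids)) stop("model '", model$name, "' has no child vertex to fit")
  miss <- setdiff(model$vertices, names(data))
  if (length(miss))
    stop("data lack model variable(s): ", paste(miss, collapse = ", "))
  fits <- list()
  for (v in kids) {
    pa <- parents(model, v)
    vars <- c(v, pa)
    d <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
    if (!nrow(d)) stop("no complete observations for equation of ", v)
    d[[".y"]] <- response_values(model, d, v)
    for (p in pa)
      if (model$transform[[p]] == "log") d[[p]] <- log(as.numeric(d[[p]]))
    terms <- if (smooth) sprintf("s(%s, k = %d)", pa, k) else pa
    fml <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
    fit <- mgcv::gam(fml, family = glm_family_for(model$family[[v]]),
                     data = d, method = method)
    if (!fit$converged)
      stop("structural equation for ", v, " did not converge")
    if (model$family[[v]] == "poisson") {
      disp <- sum(stats::residuals(fit, type = "pearson")^2) /
        stats::df.residual(fit)
      if (is.finite(disp) && disp > overdispersion_threshold)
        warning(sprintf(
          "poisson equation for %s is overdispersed (Pearson ratio %.2f)",
          v, disp))
    }
    fits[[v]] <- fit
  }
  structure(list(model = model, fits = fits, smooth = smooth, k = k,
                 method = method),
            class = "structural_fit")
}

#' Total parameter count of a fitted causal model
#'
#' Sums the estimated parameters of the structural equations: intercepts
#' plus coefficients, with smooth terms contributing their effective
#' degrees of freedom (hence K may be fractional). Equations exist only for
#' child vertices; parentless vertices contribute nothing by default, or an
#' intercept-only equation each when \code{count_parentless = TRUE}.
#'
#' @param sfit A \code{"structural_fit"}.
#' @param count_parentless Also count one intercept per parentless vertex.
#' @return K, the (possibly fractional) total number of estimated
#'   parameters.
#' @export
count_parameters <- function(sfit, count_parentless = FALSE) {
  stopifnot(inherits(sfit, "structural_fit"))
  K <- sum(vapply(sfit$fits, function(f) sum(f$edf), numeric(1)))
  if (count_parentless) {
    np <- sum(!sfit$model$vertices %in% names(sfit$fits))
    K <- K + np
  }
  K
}

#' Percent deviance explained by one predictor
#'
#' The equation is refitted without the predictor while every remaining
#' smooth keeps the smoothing parameter estimated in the full fit, and the
#' deviance increase is expressed as a percentage of the null deviance:
#' \eqn{D^2 = 100 (dev_{reduced} - dev_{full}) / dev_{null}}. With frozen
#' penalties the reduced model is nested in the full one, so the value is
#' non-negative (numerical noise below zero is floored at 0). For a single
#' linear Gaussian predictor this reduces to 100 times the OLS
#' \eqn{R^2}.
#'
#' @param sfit A \code{"structural_fit"}.
#' @param response Child vertex whose equation is examined.
#' @param predictor Parent to drop.
#' @return Percent deviance explained (non-negative scalar).
#' @export
deviance_explained <- function(sfit, response, predictor) {
  stopifnot(inherits(sfit, "structural_fit"))
  fit <- sfit$fits[[response]]
  if (is.null(fit)) stop("no fitted equation for ", response)
  if (fit$null.deviance <= 0)
    stop("null deviance of the ", response, " equation is zero; D^2 undefined")
  pa <- parents(sfit$model, response)
  if (!predictor %in% pa)
    stop("term ", predictor, " not found in the fitted equation")
  keep <- setdiff(pa, predictor)
  terms <- if (sfit$smooth) sprintf("s(%s, k = %d)", keep, sfit$k) else keep
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  sp <- NULL
  if (sfit$smooth && length(keep)) {
    smooth_vars <- vapply(fit$smooth, function(s) s$term[1], character(1))
    sp <- unname(fit$sp[match(keep, smooth_vars)])  # freeze remaining penalties
  }
  refit <- mgcv::gam(stats::as.formula(paste(".y ~", rhs)),
                     family = fit$family,
                     data = fit$model, sp = sp, method = sfit$method)
  d2 <- 100 * (stats::deviance(refit) - stats::deviance(fit)) /
    fit$null.deviance
  max(0, d2)
}

term_pvalues <- function(fit) {
  sm <- summary(fit)
  out <- numeric(0)
  if (!is.null(sm$s.table) && nrow(sm$s.table)) {
    v <- vapply(fit$smooth, function(s) s$term[1], character(1))
    p <- sm$s.table[, "p-value"]
    out <- c(out, stats::setNames(as.numeric(p), v))
  }
  if (!is.null(sm$p.table) && nrow(sm$p.table)) {
    pt <- sm$p.table
    keep <- rownames(pt) != "(Intercept)"
    out <- c(out, stats::setNames(as.numeric(pt[keep, 4]),
                                  rownames(pt)[keep]))
  }
  out
}

term_direction <- function(fit, predictor) {
  dat <- fit$model
  grid <- dat[rep(1, 50), , drop = FALSE]
  for (nm in names(grid)) if (is.numeric(grid[[nm]]))
    grid[[nm]] <- stats::median(dat[[nm]], na.rm = TRUE)
  xs <- seq(min(dat[[predictor]]), max(dat[[predictor]]), length.out = 50)
  grid[[predictor]] <- xs
  eta <- as.numeric(stats::predict(fit, newdata = grid, type = "link"))
  dif <- diff(eta)
  if (all(dif >= -1e-10)) "positive"
  else if (all(dif <= 1e-10)) "negative"
  else "nonmonotone"
}

#' Per-path report for a fitted causal model
#'
#' For every path (edge) of the model, the p-value of the predictor's term
#' in its structural equation, the direction of the estimated relationship,
#' and the percent deviance explained by drop-term refit. Following the
#' reporting convention for these tables, \eqn{D^2} is only reported
#' (non-\code{NA}) for terms significant at \code{alpha}.
#'
#' @param sfit A \code{"structural_fit"}.
#' @param alpha Significance threshold gating the \eqn{D^2} column.
#' @return A data frame with columns \code{response}, \code{predictor},
#'   \code{p_value}, \code{direction}, \code{deviance_explained_pct}.
#' @export
path_report <- function(sfit, alpha = 0.05) {
  stopifnot(inherits(sfit, "structural_fit"))
  rows <- list()
  for (v in names(sfit$fits)) {
    fit <- sfit$fits[[v]]
    pv <- term_pvalues(fit)
    for (p in parents(sfit$model, v)) {
      pval <- unname(pv[[p]])
      d2 <- if (!is.na(pval) && pval < alpha)
        deviance_explained(sfit, v, p) else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        response = v, predictor = p, p_value = pval,
        direction = term_direction(fit, p),
        deviance_explained_pct = d2, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Format a path report like the published path tables
#'
#' @param report Output of \code{\link{path_report}}.
#' @return A character matrix with columns Response, Predictor, P, D2;
#'   non-significant terms show \code{"-"} in the D2 column.
#' @export
format_path_report <- function(report) {
  fmt_p <- ifelse(report$p_value < 0.001, "<0.001",
                  formatC(report$p_value, digits = 2, format = "fg"))
  fmt_d <- ifelse(is.na(report$deviance_explained_pct), "-",
                  formatC(report$deviance_explained_pct, format = "f",
                          digits = 1))
  cbind(Response = report$response, Predictor = report$predictor,
        P = fmt_p, D2 = fmt_d)
}

#' @export
print.structural_fit <- function(x, ...) {
  cat("Structural equations of model '", x$model$name, "' (",
      if (x$smooth) paste0("smooth terms, k = ", x$k) else "linear terms",
      ")\n", sep = "")
  print(format_path_report(path_report(x)), quote = FALSE)
  invisible(x)
}
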