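#' Geometric feature recipe for diameter-based weight estimation
#'
#' The default predictor set for the partial least squares weight
#' estimator: the two caliper diameters and their monomials up to the cubic
#' products that span an ellipsoid-volume relationship —
#' \code{dmax}, \code{dmin}, \code{dmax^2}, \code{dmin^2},
#' \code{dmax*dmin}, \code{dmax^2*dmin}, \code{dmax*dmin^2}. Seven features
#' support the seven-component fit.
#'
#' @param dmax_mm,dmin_mm Maximum and minimum fruitbody diameters (mm).
#' @return Numeric matrix with one named column per feature.
#' @export
pls_features <- function(dmax_mm, dmin_mm) {
  cbind(dmax = dmax_mm,
        dmin = dmin_mm,
        dmax2 = dmax_mm^2,
        dmin2 = dmin_mm^2,
        dmax_dmin = dmax_mm * dmin_mm,
        dmax2_dmin = dmax_mm^2 * dmin_mm,
        dmax_dmin2 = dmax_mm * dmin_mm^2)
}

#' Fit a partial least squares fruitbody-weight estimator
#'
#' Univariate PLS regression (orthogonal-scores NIPALS) of fresh weight on
#' a feature matrix derived from the caliper diameters, used to impute the
#' weight of fruitbodies for which only diameters were recorded. Features
#' and response are centered internally (and features optionally scaled),
#' so predictions are invariant to centering conventions. Weight is
#' modelled on the raw gram scale; validation is done on the log scale
#' (see \code{\link{validate_pls}}).
#'
#' @param records Harvest data frame with \code{dmax_mm}, \code{dmin_mm}
#'   and \code{weight_g} present, or \code{NULL} when \code{X} and \code{y}
#'   are given directly.
#' @param n_components Number of PLS components (default 7, matching the
#'   seven default features).
#' @param X Optional feature matrix overriding the default recipe.
#' @param y Optional response vector (grams) when \code{X} is given.
#' @param scale Scale features to unit variance before fitting (default
#'   \code{TRUE}).
#' @return A \code{"pls_weight_model"} with the loadings, centering
#'   constants, per-component cumulative fraction of response variance
#'   explained (\code{explained}), and the training size.
#' @export
fit_pls <- function(records = NULL, n_components = 7, X = NULL, y = NULL,
                    scale = TRUE) {
  if (is.null(X)) {
    need <- c("dmax_mm", "dmin_mm", "weight_g")
    miss <- setdiff(need, names(records))
    if (length(miss))
      stop("records lack column(s): ", paste(miss, collapse = ", "))
    ok <- stats::complete.cases(records[need])
    X <- pls_features(records$dmax_mm[ok], records$dmin_mm[ok])
    y <- records$weight_g[ok]
  }
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.numeric(y)
  n <- nrow(X)
  if (n != length(y)) stop("X and y sizes disagree")
  if (n <= n_components)
    stop("training size (", n, ") must exceed the number of components")
  mu_x <- colMeans(X)
  sd_x <- apply(X, 2, stats::sd)
  if (scale) {
    if (any(sd_x == 0)) stop("constant feature column: ",
                             paste(colnames(X)[sd_x == 0], collapse = ", "))
    Xs <- sweep(sweep(X, 2, mu_x), 2, sd_x, "/")
  } else {
    Xs <- sweep(X, 2, mu_x)
    sd_x <- rep(1, ncol(X))
  }
  r <- qr(Xs)$rank
  if (r < n_components)
    stop("feature matrix has rank ", r, " < ", n_components,
         " components; use fewer components")
  mu_y <- mean(y)
  ys <- y - mu_y
  p <- ncol(X)
  W <- P <- matrix(0, p, n_components)
  q <- numeric(n_components)
  E <- Xs; f <- ys
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12)
      stop("residual covariance vanished at component ", a,
           "; use fewer components")
    w <- w / nw
    t_a <- drop(E %*% w)
    tt <- sum(t_a^2)
    P[, a] <- drop(crossprod(E, t_a)) / tt
    q[a] <- sum(f * t_a) / tt
    E <- E - tcrossprod(t_a, P[, a])
    f <- f - q[a] * t_a
    W[, a] <- w
  }
  # cumulative fraction of response variance explained per component count
  tss <- sum(ys^2)
  explained <- vapply(seq_len(n_components), function(a) {
    B <- W[, 1:a, drop = FALSE] %*%
      solve(crossprod(P[, 1:a, drop = FALSE], W[, 1:a, drop = FALSE]),
            q[1:a])
    1 - sum((ys - Xs %*% B)^2) / tss
  }, numeric(1))
  structure(list(n_components = n_components, features = colnames(X),
                 weights = W, loadings = P, q = q,
                 mu_x = mu_x, sd_x = sd_x, mu_y = mu_y,
                 explained = explained, n = n),
            class = "pls_weight_model")
}

#' Predict fruitbody weight from diameters
#'
#' @param object A \code{"pls_weight_model"}.
#' @param newdata Harvest data frame with \code{dmax_mm}/\code{dmin_mm}
#'   (when the model was fitted with the default recipe), or a feature
#'   matrix with the model's columns.
#' @param n_components Number of components to use (default: all fitted).
#' @param ... Unused.
#' @return Numeric vector of predicted fresh weights (grams).
#' @export
predict.pls_weight_model <- function(object, newdata,
                                     n_components = object$n_components,
                                     ...) {
  if (n_components > object$n_components)
    stop("model was fitted with ", object$n_components, " components")
  X <- if (is.matrix(newdata)) newdata
       else if (all(c("dmax_mm", "dmin_mm") %in% names(newdata)))
         pls_features(newdata$dmax_mm, newdata$dmin_mm)
       else as.matrix(newdata)
  if (!is.null(colnames(X)) && all(object$features %in% colnames(X)))
    X <- X[, object$features, drop = FALSE]
  if (ncol(X) != length(object$features))
    stop("newdata features do not match the fitted recipe")
  Xs <- sweep(sweep(X, 2, object$mu_x), 2, object$sd_x, "/")
  a <- seq_len(n_components)
  B <- object$weights[, a, drop = FALSE] %*%
    solve(crossprod(object$loadings[, a, drop = FALSE],
                    object$weights[, a, drop = FALSE]),
          object$q[a])
  drop(object$mu_y + Xs %*% B)
}

#' Validate a PLS weight model on held-out fruitbodies
#'
#' Ordinary regression of log observed weight on log predicted weight;
#' returns the R-squared, the slope and the p-value of the slope.
#' Non-positive predictions are excluded with a warning before taking
#' logs.
#'
#' @param model A \code{"pls_weight_model"}.
#' @param records Held-out harvest data frame with observed
#'   \code{weight_g} (and diameters for the default recipe).
#' @return List with \code{r_squared}, \code{slope}, \code{p_value},
#'   \code{n}.
#' @export
validate_pls <- function(model, records) {
  pred <- stats::predict(model, records)
  obs <- records$weight_g
  ok <- stats::complete.cases(cbind(pred, obs))
  pred <- pred[ok]; obs <- obs[ok]
  if (any(pred <= 0)) {
    warning(sum(pred <= 0), " non-positive prediction(s) excluded before log")
    keep <- pred > 0
    pred <- pred[keep]; obs <- obs[keep]
  }
  if (any(obs <= 0)) stop("observed weights must be positive")
  fit <- stats::lm(log(obs) ~ log(pred))
  sm <- summary(fit)
  list(r_squared = sm$r.squared,
       slope = unname(stats::coef(fit)[2]),
       p_value = unname(sm$coefficients[2, 4]),
       n = length(obs))
}

#' @export
print.pls_weight_model <- function(x, ...) {
  cat("PLS fruitbody-weight model: ", x$n_components, " components, ",
      length(x$features), " features, n = ", x$n, "\n", sep = "")
  cat(sprintf("In-sample variance explained: %.1f%%\n",
              100 * x$explained[x$n_components]))
  invisible(x)
}

#' Serialize / restore a PLS weight model as JSON
#' @param model A \code{"pls_weight_model"}.
#' @param path File path.
#' @return \code{read_pls}: the restored model.
#' @export
write_pls <- function(model, path) {
  doc <- lapply(unclass(model), function(v) if (is.matrix(v))
    list(dim = dim(v), data = as.numeric(v)) else v)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pls
#' @export
read_pls <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("weights", "loadings"))
    doc[[nm]] <- matrix(doc[[nm]]$data, doc[[nm]]$dim[1], doc[[nm]]$dim[2])
  for (nm in c("mu_x", "sd_x"))
    doc[[nm]] <- stats::setNames(as.numeric(doc[[nm]]), doc$features)
  structure(doc[c("n_components", "features", "weights", "loadings", "q",
                  "mu_x", "sd_x", "mu_y", "explained", "n")],
            class = "pls_weight_model")
}
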