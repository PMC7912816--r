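#' Apply a model's variable transforms to a data frame
#'
#' Variables declared with a \code{"log"} transform (the weights) are
#' log-transformed; everything else is returned as numeric. Used by the
#' partial-correlation claim engine and when a transformed variable enters
#' another equation as a predictor.
#'
#' @param model A \code{"causal_model"}.
#' @param data Data frame containing the model's vertices.
#' @return The data frame with transforms applied to the model columns.
#' @export
apply_transforms <- function(model, data) {
  miss <- setdiff(model$vertices, names(data))
  if (length(miss))
    stop("data lack model variable(s): ", paste(miss, collapse = ", "))
  for (v in model$vertices) {
    col <- as.numeric(data[[v]])
    if (model$transform[[v]] == "log") {
      if (any(col <= 0, na.rm = TRUE))
        stop("variable ", v, " must be positive for its log transform")
      col <- log(col)
    }
    data[[v]] <- col
  }
  data
}

#' Partial-correlation test of conditional independence
#'
#' The partial correlation of \code{x} and \code{y} given \code{z} is
#' computed from the residuals of the linear projections of \code{x} and
#' \code{y} on \code{z} (with intercept), and converted to a two-sided
#' p-value through \eqn{t = r \sqrt{(n - |z| - 2) / (1 - r^2)}} on
#' \eqn{n - |z| - 2} degrees of freedom.
#'
#' @param data Data frame of numeric variables (already transformed).
#' @param x,y Variable names.
#' @param given Character vector of conditioning variables (may be empty).
#' @return A \code{"claim_result"}: list with \code{x}, \code{y},
#'   \code{given}, \code{n}, \code{statistic} (the partial correlation),
#'   \code{p_value}, \code{method}.
#' @export
partial_correlation_test <- function(data, x, y, given = character(0)) {
  vars <- c(x, y, given)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("unknown variable(s): ", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  n <- nrow(d)
  df <- n - length(given) - 2
  if (df < 1)
    stop("too few observations (n = ", n, ") for |z| = ", length(given))
  xv <- as.numeric(d[[x]]); yv <- as.numeric(d[[y]])
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0)
    stop("constant variable: correlation undefined for ",
         if (stats::sd(xv) == 0) x else y)
  if (length(given)) {
    Z <- cbind(1, as.matrix(d[given]))
    q <- qr(Z)
    xv <- qr.resid(q, xv)
    yv <- qr.resid(q, yv)
    if (stats::sd(xv) == 0 || stats::sd(yv) == 0)
      stop("variable collinear with conditioning set; partial correlation undefined")
  }
  r <- sum(scale(xv, scale = FALSE) * scale(yv, scale = FALSE)) /
    sqrt(sum(scale(xv, scale = FALSE)^2) * sum(scale(yv, scale = FALSE)^2))
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    tstat <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  }
  structure(list(x = x, y = y, given = given, n = n, statistic = r,
                 p_value = p, method = "partial_correlation"),
            class = "claim_result")
}

#' Family-appropriate regression test of an independence claim
#'
#' Fits a generalized regression of the claim's designated response on the
#' conditioning set plus the other pair member (identity link for Gaussian,
#' log link for Poisson and Gamma responses; a Gaussian response with a
#' declared log transform is fitted on the log scale) and returns the Wald
#' p-value of the other pair member's coefficient.
#'
#' @param data Data frame with raw (untransformed) analysis variables.
#' @param claim An \code{"independence_claim"}.
#' @param model The \code{"causal_model"} supplying families and transforms.
#' @return A \code{"claim_result"} with method \code{"regression_wald"}.
#' @export
regression_claim_test <- function(data, claim, model) {
  resp <- claim$response
  other <- setdiff(c(claim$x, claim$y), resp)
  preds <- c(claim$given, other)
  vars <- c(resp, preds)
  d <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  n <- nrow(d)
  if (n <= length(preds) + 2)
    stop("too few observations for claim ", claim$x, " _||_ ", claim$y)
  fam <- model$family[[resp]]
  if (fam %in% c("poisson", "gamma") && any(d[[resp]] < 0))
    stop("response ", resp, " must be non-negative for a ", fam, " family")
  if (fam == "gamma" && any(d[[resp]] <= 0))
    stop("response ", resp, " must be positive for a gamma family")
  # predictors enter on their transform scale
  for (p in preds)
    if (model$transform[[p]] == "log") d[[p]] <- log(as.numeric(d[[p]]))
  yname <- resp
  if (fam == "gaussian" && model$transform[[resp]] == "log") {
    if (any(d[[resp]] <= 0))
      stop("response ", resp, " must be positive for its log transform")
    d[[resp]] <- log(as.numeric(d[[resp]]))
  }
  if (stats::sd(d[[yname]]) == 0)
    stop("degenerate fit: response ", resp, " is constant")
  glm_family <- switch(fam,
                       gaussian = stats::gaussian(),
                       poisson = stats::poisson(link = "log"),
                       gamma = stats::Gamma(link = "log"))
  fml <- stats::reformulate(preds, response = yname)
  fit <- stats::glm(fml, family = glm_family, data = d)
  if (!fit$converged)
    stop("regression for claim ", claim$x, " _||_ ", claim$y,
         " did not converge")
  ct <- summary(fit)$coefficients
  if (!other %in% rownames(ct) || is.na(ct[other, 4]))
    stop("degenerate fit: coefficient of ", other, " not estimable in claim ",
         claim$x, " _||_ ", claim$y)
  structure(list(x = claim$x, y = claim$y, given = claim$given, n = n,
                 statistic = ct[other, 3], p_value = ct[other, 4],
                 method = "regression_wald"),
            class = "claim_result")
}

#' Test every claim in a model's basis set
#'
#' @param model A \code{"causal_model"}.
#' @param data Data frame of raw analysis variables.
#' @param engine \code{"partial_correlation"} (default; variables are first
#'   put on their transform scale) or \code{"regression"} (family-specific
#'   Wald tests).
#' @return A list of \code{"claim_result"} objects, one per basis claim.
#' @export
test_claims <- function(model, data,
                        engine = c("partial_correlation", "regression")) {
  engine <- match.arg(engine)
  claims <- basis_set(model)
  if (engine == "partial_correlation") {
    td <- apply_transforms(model, data)
    lapply(claims, function(cl)
      partial_correlation_test(td, cl$x, cl$y, cl$given))
  } else {
    lapply(claims, function(cl) regression_claim_test(data, cl, model))
  }
}

#' @export
print.claim_result <- function(x, ...) {
  cond <- if (length(x$given)) paste(x$given, collapse = ", ") else "{}"
  cat(sprintf("%s _||_ %s | %s : stat = %.3f, p = %.4g (n = %d, %s)\n",
              x$x, x$y, cond, x$statistic, x$p_value, x$n, x$method))
  invisible(x)
}
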