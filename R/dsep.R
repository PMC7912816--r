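#' Fisher's C statistic
#'
#' Combines the null probabilities of the independence claims in a basis
#' set: \eqn{C = -2 \sum \ln p_i}, distributed as chi-square on \eqn{2k}
#' degrees of freedom when the causal model is correct.
#'
#' @param p_values Numeric vector of claim p-values in (0, 1].
#' @return List with \code{C}, \code{df} (\eqn{2k}) and \code{p_value}
#'   (upper-tail chi-square probability).
#' @examples
#' fishers_c(0.5)   # C = -2 log 0.5 = 1.386, df = 2
#' @export
fishers_c <- function(p_values) {
  if (!length(p_values)) stop("empty p-value list")
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  if (any(p_values == 0)) {
    warning("claim p-value of 0 floored at the smallest representable ",
            "positive number; Fisher's C is effectively infinite")
    p_values <- pmax(p_values, .Machine$double.xmin)
  }
  C <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  list(C = C, df = df,
       p_value = stats::pchisq(C, df = df, lower.tail = FALSE))
}

#' Null probability of a Fisher's C value
#'
#' Upper-tail chi-square probability of an already-computed C statistic;
#' handy for re-deriving the P column of a model-fit table from its C and
#' df columns.
#'
#' @param C Fisher's C statistic.
#' @param df Degrees of freedom (twice the claim count).
#' @return The p-value.
#' @examples
#' fishers_c_tail(22.3, 14)
#' @export
fishers_c_tail <- function(C, df) {
  stats::pchisq(C, df = df, lower.tail = FALSE)
}

#' Small-sample-corrected AIC for a d-separation test
#'
#' \eqn{AICc = C + 2 K n / (n - K - 1)}, with \eqn{C} the Fisher statistic,
#' \eqn{K} the total number of estimated parameters of the structural
#' equations and \eqn{n} the sample size.
#'
#' @param C Fisher's C.
#' @param K Parameter count (possibly fractional; see
#'   \code{\link{count_parameters}}).
#' @param n Sample size.
#' @return The AICc value.
#' @export
aicc <- function(C, K, n) {
  if (n <= K + 1)
    stop("AICc undefined: n = ", n, " must exceed K + 1 = ", K + 1)
  C + 2 * K * n / (n - K - 1)
}

#' d-separation test of one causal model against data
#'
#' Runs the full d-sep procedure for a single model: enumerate the basis
#' set, compute the null probability of each claim, combine them into
#' Fisher's C with its chi-square p-value, and (for models not rejected)
#' fit the structural equations to obtain the parameter count K and AICc.
#' A model with Fisher's C p-value above \code{alpha} is considered
#' consistent with the data.
#'
#' @param model A \code{"causal_model"}.
#' @param data Data frame of raw analysis variables.
#' @param engine Claim-testing engine, \code{"partial_correlation"}
#'   (default) or \code{"regression"}; see \code{\link{test_claims}}.
#' @param alpha Consistency threshold on the Fisher's C p-value.
#' @param fit_K When to fit structural equations for K/AICc:
#'   \code{"consistent"} (default; rejected models report \code{NA}, as the
#'   published comparison tables leave them blank), \code{"always"}, or
#'   \code{"never"}.
#' @param smooth,k,method Passed to \code{\link{fit_structural_equations}}.
#' @return A \code{"dsep_result"}: list with \code{model} (name),
#'   \code{claim_results}, \code{k} (claim count), \code{C}, \code{df},
#'   \code{p_value}, \code{n}, \code{K}, \code{AICc}, \code{consistent}.
#' @export
dsep_test <- function(model, data,
                      engine = c("partial_correlation", "regression"),
                      alpha = 0.05,
                      fit_K = c("consistent", "always", "never"),
                      smooth = TRUE, k = 4, method = "REML") {
  engine <- match.arg(engine)
  fit_K <- match.arg(fit_K)
  claim_results <- test_claims(model, data, engine)
  n <- min(vapply(claim_results, function(cr) cr$n, numeric(1)))
  fc <- fishers_c(vapply(claim_results, function(cr) cr$p_value, numeric(1)))
  consistent <- fc$p_value > alpha
  K <- AICc <- NA_real_
  if (fit_K == "always" || (fit_K == "consistent" && consistent)) {
    sfit <- fit_structural_equations(model, data, smooth = smooth, k = k,
                                     method = method)
    K <- count_parameters(sfit)
    AICc <- aicc(fc$C, K, n)
  }
  structure(list(model = model$name, claim_results = claim_results,
                 k = length(claim_results), C = fc$C, df = fc$df,
                 p_value = fc$p_value, n = n, K = K, AICc = AICc,
                 alpha = alpha, consistent = consistent),
            class = "dsep_result")
}

#' @export
print.dsep_result <- function(x, ...) {
  cat(sprintf("d-sep test of model '%s': C = %.1f (df = %d, P = %.2f), n = %d\n",
              x$model, x$C, x$df, x$p_value, x$n))
  if (!is.na(x$K))
    cat(sprintf("  K = %.1f, AICc = %.1f\n", x$K, x$AICc))
  cat("  ", if (x$consistent) "consistent" else "rejected",
      sprintf(" at alpha = %.2f\n", x$alpha), sep = "")
  invisible(x)
}

#' Compare candidate causal models by AICc and Akaike weights
#'
#' Models rejected by the Fisher's C test (p-value at or below
#' \code{alpha}) are excluded from the weight computation, mirroring the
#' convention of leaving K, AICc and W blank for rejected models. Among the
#' included models, \eqn{\Delta_i = AICc_i - \min AICc} and
#' \eqn{W_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)}.
#'
#' @param results List of \code{"dsep_result"} objects (with K/AICc
#'   available for the consistent models).
#' @param alpha Rejection threshold; set to 0 to include every model.
#' @return A \code{"model_comparison"}: data frame with one row per model
#'   (\code{model}, \code{C}, \code{df}, \code{p_value}, \code{K},
#'   \code{AICc}, \code{delta_AICc}, \code{weight}, \code{included}). If no
#'   model is consistent, weights are all \code{NA} and the comparison
#'   carries a diagnostic attribute \code{"note"}.
#' @export
compare_models <- function(results, alpha = 0.05) {
  stopifnot(length(results) >= 1)
  tab <- do.call(rbind, lapply(results, function(r)
    data.frame(model = r$model, C = r$C, df = r$df, p_value = r$p_value,
               n = r$n, K = r$K, AICc = r$AICc, stringsAsFactors = FALSE)))
  tab$included <- tab$p_value > alpha & !is.na(tab$AICc)
  tab$delta_AICc <- NA_real_
  tab$weight <- NA_real_
  note <- NULL
  if (any(tab$included)) {
    inc <- tab$included
    tab$delta_AICc[inc] <- tab$AICc[inc] - min(tab$AICc[inc])
    w <- exp(-tab$delta_AICc[inc] / 2)
    tab$weight[inc] <- w / sum(w)
  } else {
    note <- "no model is consistent with the data at the chosen alpha"
  }
  structure(tab, class = c("model_comparison", "data.frame"),
            alpha = alpha, note = note)
}

#' Best model of a comparison
#' @param comparison A \code{"model_comparison"}.
#' @return The name of the top-weighted model, or \code{NA} if no model is
#'   consistent.
#' @export
best_model <- function(comparison) {
  if (!any(comparison$included)) return(NA_character_)
  comparison$model[which.max(comparison$weight)]
}

#' Format a model comparison like the published model-fit tables
#'
#' Columns \code{C (df, P)}, \code{K}, \code{AICc}, \code{W}; C and AICc to
#' one decimal, P and W to two, with \code{"-"} for models excluded from
#' the weighting.
#'
#' @param comparison A \code{"model_comparison"}.
#' @return A character matrix ready for printing.
#' @export
format_comparison <- function(comparison) {
  p_fmt <- ifelse(comparison$p_value < 0.001, "<0.001",
                  formatC(comparison$p_value, format = "f", digits = 2))
  w_fmt <- ifelse(!comparison$included, "-",
                  ifelse(comparison$weight < 0.01, "<0.01",
                         formatC(comparison$weight, format = "f", digits = 2)))
  cbind(Model = comparison$model,
        `C (df, P)` = sprintf("%.1f (%d, %s)", comparison$C, comparison$df,
                              p_fmt),
        K = ifelse(comparison$included,
                   formatC(comparison$K, format = "f", digits = 1), "-"),
        AICc = ifelse(comparison$included,
                      formatC(comparison$AICc, format = "f", digits = 1), "-"),
        W = w_fmt)
}

#' @export
print.model_comparison <- function(x, ...) {
  print(format_comparison(x), quote = FALSE)
  if (!is.null(attr(x, "note"))) cat("note:", attr(x, "note"), "\n")
  invisible(x)
}

#' Akaike weights from AICc values
#'
#' @param AICc Numeric vector of AICc values.
#' @return Weights summing to 1: \eqn{\exp(-\Delta_i/2)} normalized.
#' @examples
#' akaike_weights(c(36.9, 40.7, 41.4))
#' @export
akaike_weights <- function(AICc) {
  delta <- AICc - min(AICc)
  w <- exp(-delta / 2)
  w / sum(w)
}
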