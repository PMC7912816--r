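#' Run the d-separation model comparison over a harvest dataset
#'
#' End-to-end driver: builds the analysis table for the requested dig type
#' (cluster analyses automatically work on the per-dig summaries and drop
#' maturity, which is unavailable for clusters), optionally splits it by
#' soil typology, runs \code{\link{dsep_test}} for every candidate model on
#' every subset, and assembles a \code{\link{compare_models}} table per
#' subset.
#'
#' @param records Harvest data frame (see \code{\link{read_harvest}}).
#' @param models List of \code{"causal_model"} objects, or a character
#'   vector of built-in names such as \code{c("single_A", "single_B")}; by
#'   default the built-ins matching \code{dig_type}.
#' @param dig_type \code{"single"} or \code{"cluster"}.
#' @param by_typology Analyse each soil typology separately (default) or
#'   pool them.
#' @param engine,alpha,smooth,k,method Passed to \code{\link{dsep_test}}.
#' @return A named list (one element per subset) of
#'   \code{"model_comparison"} objects; each carries its per-model
#'   \code{"dsep_result"} list in attribute \code{"results"}.
#' @export
dsep_compare <- function(records, models = NULL,
                         dig_type = c("single", "cluster"),
                         by_typology = TRUE,
                         engine = c("partial_correlation", "regression"),
                         alpha = 0.05, smooth = TRUE, k = 4,
                         method = "REML") {
  dig_type <- match.arg(dig_type)
  engine <- match.arg(engine)
  if (is.null(models))
    models <- grep(paste0("^", dig_type), names(truffle_models()),
                   value = TRUE)
  if (is.character(models)) {
    builtin <- truffle_models()
    unknown <- setdiff(models, names(builtin))
    if (length(unknown))
      stop("unknown model name(s): ", paste(unknown, collapse = ", "),
           "; built-ins are: ", paste(names(builtin), collapse = ", "))
    models <- builtin[models]
  }
  tab <- analysis_table(records, dig_type)
  subsets <- if (by_typology) split(tab, tab$typology) else list(all = tab)
  subsets <- Filter(nrow, subsets)
  if (!length(subsets)) stop("no observations after filtering")
  lapply(subsets, function(d) {
    res <- lapply(models, dsep_test, data = d, engine = engine,
                  alpha = alpha, smooth = smooth, k = k, method = method)
    cmp <- compare_models(res, alpha = alpha)
    attr(cmp, "results") <- res
    cmp
  })
}

#' Fit and report the paths of a selected model
#'
#' Fits the structural equations of one model on one data subset and
#' returns the per-path report (p-value, direction, percent deviance
#' explained). Fitting a model that the d-sep test rejected on the same
#' data is refused unless \code{force = TRUE}.
#'
#' @param records Harvest data frame.
#' @param model A \code{"causal_model"} or a built-in name.
#' @param dig_type \code{"single"} or \code{"cluster"}.
#' @param typology Optional typology filter.
#' @param check_consistency Run the d-sep test first and warn/stop if the
#'   model is rejected.
#' @param force Proceed even when the model is rejected.
#' @param alpha,smooth,k,method As in \code{\link{dsep_test}}.
#' @return A list with the \code{"structural_fit"} (\code{fit}) and the
#'   \code{path_report} data frame (\code{report}).
#' @export
fit_best_model <- function(records, model,
                           dig_type = c("single", "cluster"),
                           typology = NULL, check_consistency = TRUE,
                           force = FALSE, alpha = 0.05, smooth = TRUE,
                           k = 4, method = "REML") {
  dig_type <- match.arg(dig_type)
  if (is.character(model)) {
    builtin <- truffle_models()
    if (!model %in% names(builtin))
      stop("unknown model name: ", model, "; built-ins are: ",
           paste(names(builtin), collapse = ", "))
    model <- builtin[[model]]
  }
  tab <- analysis_table(records, dig_type, typology = typology)
  if (!nrow(tab)) stop("no observations after filtering")
  miss <- setdiff(model$vertices, names(tab))
  if (length(miss))
    stop("analysis table lacks model variable(s): ",
         paste(miss, collapse = ", "))
  if (check_consistency) {
    dt <- dsep_test(model, tab, alpha = alpha, fit_K = "never")
    if (!dt$consistent) {
      msg <- sprintf("model '%s' is rejected by the d-sep test (P = %.3f)",
                     model$name, dt$p_value)
      if (!force) stop(msg, "; use force = TRUE to fit it anyway")
      warning(msg, "; fitting anyway")
    }
  }
  sfit <- fit_structural_equations(model, tab, smooth = smooth, k = k,
                                   method = method)
  list(fit = sfit, report = path_report(sfit, alpha = alpha))
}

#' Write a model-comparison table to CSV
#' @param comparisons Output of \code{\link{dsep_compare}} (a named list of
#'   comparisons) or a single \code{"model_comparison"}.
#' @param path CSV file path.
#' @return The path, invisibly.
#' @export
write_comparison_csv <- function(comparisons, path) {
  if (inherits(comparisons, "model_comparison"))
    comparisons <- list(all = comparisons)
  rows <- do.call(rbind, lapply(names(comparisons), function(nm) {
    x <- as.data.frame(comparisons[[nm]])
    cbind(subset = nm, x)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
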