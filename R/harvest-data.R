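harvest_columns <- function() {
  c("season", "block", "typology", "dig_id", "dig_type", "harvest_date",
    "depth_class", "weight_g", "dmax_mm", "dmin_mm", "shape_index",
    "maturity", "role")
}

typology_levels <- function() c("substrate", "BS1", "BS2", "BS3")

#' Validate a harvest dataset
#'
#' Row-level checks of the harvest schema: positive weights, shape index in
#' 1..9, maturity in [0, 1] when present, depth class at least 1,
#' \code{dmax_mm >= dmin_mm} when both are present, known typology and dig
#' type, parseable dates; and dig-level checks: a single dig has exactly one
#' record with role \code{"single"}, a cluster dig has at least two records
#' with exactly one role \code{"largest"} carrying the maximal weight.
#'
#' @param x A data frame with the harvest schema columns.
#' @return A character vector of problems (empty if the data are valid);
#'   each message names the offending row or dig.
#' @export
validate_harvest <- function(x) {
  problems <- character(0)
  need <- setdiff(harvest_columns(), c("dmax_mm", "dmin_mm", "maturity"))
  miss <- setdiff(need, names(x))
  if (length(miss))
    return(paste0("missing mandatory column(s): ", paste(miss, collapse = ", ")))
  note <- function(rows, what) {
    if (length(rows))
      problems <<- c(problems,
                     paste0("row ", rows, ": ", what))
  }
  note(which(!is.finite(x$weight_g) | x$weight_g <= 0),
       "weight_g must be a positive number")
  note(which(!x$shape_index %in% 1:9), "shape_index must be an integer in 1..9")
  note(which(!is.na(x$maturity) & (x$maturity < 0 | x$maturity > 1)),
       "maturity must lie in [0, 1]")
  note(which(!is.finite(x$depth_class) | x$depth_class < 1 |
               x$depth_class != round(x$depth_class)),
       "depth_class must be a positive integer interval index")
  note(which(!x$typology %in% typology_levels()),
       paste0("typology must be one of ",
              paste(typology_levels(), collapse = ", ")))
  note(which(!x$dig_type %in% c("single", "cluster")),
       "dig_type must be 'single' or 'cluster'")
  note(which(!x$role %in% c("single", "largest", "other")),
       "role must be 'single', 'largest' or 'other'")
  dt <- suppressWarnings(as.Date(x$harvest_date))
  note(which(is.na(dt)), "harvest_date is not an ISO-8601 date")
  if (all(c("dmax_mm", "dmin_mm") %in% names(x))) {
    both <- !is.na(x$dmax_mm) & !is.na(x$dmin_mm)
    note(which(both & x$dmax_mm < x$dmin_mm), "dmax_mm must be >= dmin_mm")
    note(which(!is.na(x$dmax_mm) & x$dmax_mm <= 0), "dmax_mm must be positive")
    note(which(!is.na(x$dmin_mm) & x$dmin_mm <= 0), "dmin_mm must be positive")
  }
  for (id in unique(x$dig_id)) {
    rows <- x[x$dig_id == id, , drop = FALSE]
    type <- unique(rows$dig_type)
    if (length(type) > 1) {
      problems <- c(problems, paste0("dig ", id, ": inconsistent dig_type"))
      next
    }
    if (identical(type, "single")) {
      if (nrow(rows) != 1)
        problems <- c(problems,
                      paste0("dig ", id, ": single dig must have exactly one record"))
    } else if (identical(type, "cluster")) {
      if (nrow(rows) < 2)
        problems <- c(problems,
                      paste0("dig ", id, ": cluster dig must have >= 2 records"))
      nl <- sum(rows$role == "largest")
      if (nl != 1)
        problems <- c(problems,
                      paste0("dig ", id, ": cluster dig must have exactly one 'largest' record"))
      else if (rows$weight_g[rows$role == "largest"][1] < max(rows$weight_g))
        problems <- c(problems,
                      paste0("dig ", id, ": 'largest' record does not carry the maximal weight"))
    }
  }
  problems
}

#' Read a harvest dataset from CSV
#'
#' Comma-separated, UTF-8, header required, decimal point, ISO-8601 dates.
#' One row per fruitbody; the documented columns are \code{season},
#' \code{block}, \code{typology} (substrate/BS1/BS2/BS3), \code{dig_id},
#' \code{dig_type} (single/cluster), \code{harvest_date},
#' \code{depth_class} (10-cm interval index, 1 = 0-10 cm), \code{weight_g},
#' optional \code{dmax_mm}/\code{dmin_mm}, \code{shape_index} (1-9),
#' optional \code{maturity} (0-1), \code{role} (single/largest/other).
#' A machine-readable schema descriptor ships with the package at
#' \code{system.file("extdata", "harvest-schema.json", package = "trufflepath")}.
#'
#' @param path CSV file path.
#' @param strict If \code{TRUE} (default), any invariant violation is an
#'   error naming the rows; otherwise violations are reported as warnings.
#' @return A data frame of fruitbody records.
#' @export
read_harvest <- function(path, strict = TRUE) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- setdiff(harvest_columns(), c("dmax_mm", "dmin_mm", "maturity"))
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  for (col in c("depth_class", "weight_g", "dmax_mm", "dmin_mm",
                "shape_index", "maturity")) {
    if (!col %in% names(x)) next
    v <- x[[col]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(vn))
      if (length(bad))
        stop("non-numeric value in column ", col, " at row ",
             paste(bad, collapse = ", "))
      x[[col]] <- vn
    }
  }
  problems <- validate_harvest(x)
  if (length(problems)) {
    msg <- paste(problems, collapse = "\n  ")
    if (strict) stop("invalid harvest data:\n  ", msg) else
      warning("harvest data problems:\n  ", msg)
  }
  x
}

#' @param x Harvest data frame.
#' @rdname read_harvest
#' @export
write_harvest <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Day-of-season of a harvest date
#'
#' Number of days elapsed since the start of the fruiting season; 0 on the
#' season start itself, monotone in calendar date across the year boundary.
#'
#' @param harvest_date Dates (anything \code{as.Date} accepts).
#' @param season_start Season start date; by default November 1 of the
#'   first year of the \code{season} label.
#' @param season Optional season label such as \code{"2016-2017"}, used to
#'   derive \code{season_start} when it is not given.
#' @return Integer vector of non-negative day offsets.
#' @export
harvest_day <- function(harvest_date, season_start = NULL, season = NULL) {
  if (is.null(season_start)) {
    if (is.null(season)) stop("give either season_start or season")
    season_start <- season_start_date(season)
  }
  d <- as.integer(as.Date(harvest_date) - as.Date(season_start))
  if (any(d < 0, na.rm = TRUE))
    stop("harvest_date before season_start at position ",
         paste(which(d < 0), collapse = ", "))
  d
}

#' Season start date from a season label
#'
#' A label like \code{"2016-2017"} maps to November 1 of its first year,
#' the opening of the fruiting window (November to March).
#'
#' @param season Character vector of season labels.
#' @return A \code{Date} vector.
#' @export
season_start_date <- function(season) {
  year <- sub("[-/].*$", "", as.character(season))
  if (any(!grepl("^[0-9]{4}$", year)))
    stop("season label must start with a 4-digit year, e.g. '2016-2017'")
  as.Date(paste0(year, "-11-01"))
}

#' Spore maturity index
#'
#' Proportion of sampled asci containing mature (dark brown) spores. The
#' counting protocol asks for at least 50 randomly selected asci per
#' hymenial sample; smaller counts are flagged as undersampled.
#'
#' @param n_mature Count of asci with mature spores.
#' @param n_total Total count of asci examined.
#' @param strict If \code{TRUE}, an undersampled count (\code{n_total < 50})
#'   is an error; otherwise (default) a warning.
#' @return Numeric vector in [0, 1].
#' @examples
#' maturity_index(25, 50)  # 0.5
#' @export
maturity_index <- function(n_mature, n_total, strict = FALSE) {
  if (any(n_total <= 0)) stop("n_total must be positive")
  if (any(n_mature < 0 | n_mature > n_total))
    stop("n_mature must lie in 0..n_total")
  if (any(n_total < 50)) {
    msg <- "maturity index from fewer than 50 asci is undersampled"
    if (strict) stop(msg) else warning(msg)
  }
  n_mature / n_total
}

#' Summarize cluster digs
#'
#' Each cluster dig is reduced to the weight and shape of its largest
#' fruitbody plus the combined weight of the remaining ones. The largest
#' member is the one with maximal fresh weight; ties are broken by record
#' order, which makes the reduction deterministic.
#'
#' @param records Harvest data frame.
#' @return A data frame with one row per cluster dig: \code{dig_id},
#'   \code{season}, \code{block}, \code{typology}, \code{HD_day},
#'   \code{depth_class}, \code{we_largest_g}, \code{we_rest_g},
#'   \code{shape_largest}.
#' @export
aggregate_clusters <- function(records) {
  cl <- records[records$dig_type == "cluster", , drop = FALSE]
  if (!nrow(cl))
    return(data.frame(dig_id = character(0), season = character(0),
                      block = character(0), typology = character(0),
                      HD_day = integer(0), depth_class = integer(0),
                      we_largest_g = numeric(0), we_rest_g = numeric(0),
                      shape_largest = integer(0)))
  out <- lapply(split(seq_len(nrow(cl)), factor(cl$dig_id,
                                                levels = unique(cl$dig_id))),
                function(idx) {
    rows <- cl[idx, , drop = FALSE]
    if (nrow(rows) < 2)
      stop("cluster dig ", rows$dig_id[1], " has fewer than 2 members")
    i_big <- which.max(rows$weight_g)     # first maximum: tie-break by order
    data.frame(
      dig_id = rows$dig_id[1],
      season = rows$season[1],
      block = rows$block[1],
      typology = rows$typology[1],
      HD_day = harvest_day(rows$harvest_date[1], season = rows$season[1]),
      depth_class = rows$depth_class[1],
      we_largest_g = rows$weight_g[i_big],
      we_rest_g = sum(rows$weight_g[-i_big]),
      shape_largest = rows$shape_index[i_big])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Analysis variables for the path models
#'
#' Builds the variable table the d-separation machinery works on. For
#' single fruitbodies the columns are \code{HD}, \code{depth},
#' \code{weight}, \code{shape}, \code{maturity}; for clusters, maturity is
#' unavailable and the weights are summarized per dig into \code{we_largest}
#' and \code{we_rest} (see \code{\link{aggregate_clusters}}).
#'
#' @param records Harvest data frame.
#' @param dig_type \code{"single"} or \code{"cluster"}.
#' @param typology Optional typology filter (\code{"substrate"},
#'   \code{"BS1"}, \code{"BS2"}, \code{"BS3"}).
#' @return A data frame of analysis variables, one row per single fruitbody
#'   or per cluster dig.
#' @export
analysis_table <- function(records, dig_type = c("single", "cluster"),
                           typology = NULL) {
  dig_type <- match.arg(dig_type)
  if (!is.null(typology))
    records <- records[records$typology %in% typology, , drop = FALSE]
  if (dig_type == "single") {
    s <- records[records$dig_type == "single", , drop = FALSE]
    if (is.null(s$maturity))
      stop("records lack the 'maturity' column required for ",
           "single-fruitbody analyses")
    data.frame(
      HD = harvest_day(s$harvest_date,
                       season_start = season_start_date(s$season)),
      depth = s$depth_class,
      weight = s$weight_g,
      shape = s$shape_index,
      maturity = s$maturity,
      typology = s$typology,
      stringsAsFactors = FALSE)
  } else {
    cl <- aggregate_clusters(records)
    data.frame(
      HD = cl$HD_day,
      depth = cl$depth_class,
      we_largest = cl$we_largest_g,
      we_rest = cl$we_rest_g,
      shape = cl$shape_largest,
      typology = cl$typology,
      stringsAsFactors = FALSE)
  }
}
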