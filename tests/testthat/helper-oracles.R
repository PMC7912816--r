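# Independent oracles used across the suite.

# Exhaustive path-blocking d-separation oracle: enumerate every simple
# undirected path between x and y in the DAG skeleton and apply the
# blocking rules directly (a non-collider blocks when conditioned on; a
# collider blocks unless it or one of its descendants is conditioned on).
# Deliberately naive; only for graphs of a handful of vertices.
dsep_bruteforce <- function(model, x, y, z = character(0)) {
  v <- model$vertices
  em <- model$edges
  nbrs <- function(a) unique(c(em[em[, 1] == a, 2], em[em[, 2] == a, 1]))
  desc <- function(a) {
    seen <- character(0); frontier <- a
    while (length(frontier)) {
      seen <- union(seen, frontier)
      frontier <- setdiff(unique(em[em[, 1] %in% frontier, 2]), seen)
    }
    seen
  }
  is_edge <- function(a, b) any(em[, 1] == a & em[, 2] == b)
  path_active <- function(path) {
    if (length(path) == 2) return(TRUE)
    for (i in 2:(length(path) - 1)) {
      a <- path[i - 1]; m <- path[i]; b <- path[i + 1]
      collider <- is_edge(a, m) && is_edge(b, m)
      if (collider) {
        if (!any(desc(m) %in% z)) return(FALSE)
      } else {
        if (m %in% z) return(FALSE)
      }
    }
    TRUE
  }
  found_active <- FALSE
  walk <- function(path) {
    if (found_active) return()
    last <- path[length(path)]
    if (last == y) {
      if (path_active(path)) found_active <<- TRUE
      return()
    }
    for (nb in setdiff(nbrs(last), path)) walk(c(path, nb))
  }
  walk(x)
  !found_active
}

# Random DAG on `nv` vertices: edges only from earlier to later in a random
# vertex order, each present with probability p.
random_dag <- function(nv, p = 0.4, name = "random") {
  v <- paste0("V", seq_len(nv))
  ord <- sample(v)
  edges <- list()
  for (i in seq_len(nv - 1)) for (j in (i + 1):nv)
    if (stats::runif(1) < p)
      edges[[length(edges) + 1]] <- c(ord[i], ord[j])
  causal_model(name, v, edges)
}

# Minimal well-formed harvest data frame for hand-built fixtures.
make_records <- function(weights, dig_type = "single", dig_id = NULL,
                         typology = "BS1", season = "2017-2018",
                         harvest_date = "2017-12-15", depth_class = 1,
                         shape_index = 5, maturity = NA_real_,
                         role = NULL) {
  n <- length(weights)
  if (is.null(dig_id))
    dig_id <- if (identical(dig_type, "cluster")) rep("C1", n)
              else sprintf("S%02d", seq_len(n))
  if (is.null(role))
    role <- if (identical(dig_type, "cluster"))
      ifelse(seq_len(n) == which.max(weights), "largest", "other")
    else rep("single", n)
  data.frame(season = season, block = "B1", typology = typology,
             dig_id = dig_id, dig_type = dig_type,
             harvest_date = harvest_date, depth_class = depth_class,
             weight_g = weights, dmax_mm = NA_real_, dmin_mm = NA_real_,
             shape_index = shape_index, maturity = maturity, role = role,
             stringsAsFactors = FALSE)
}
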