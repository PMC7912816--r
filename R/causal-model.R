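#' Specify a causal model as a directed acyclic graph
#'
#' A causal model is a DAG over named analysis variables, together with the
#' error family and transform used when each variable appears as a response
#' in a structural equation or an independence claim.
#'
#' @param name Label for the model (used in reports).
#' @param vertices Character vector of variable names. Their order is kept
#'   and used as the tie-break when several topological orders exist.
#' @param edges A list of length-2 character vectors, or a two-column
#'   matrix, each row/element a directed edge \code{c(parent, child)}.
#' @param family Named character vector mapping vertices to one of
#'   \code{"gaussian"}, \code{"poisson"}, \code{"gamma"}. Vertices not named
#'   default to \code{"gaussian"}.
#' @param transform Named character vector mapping vertices to
#'   \code{"identity"} or \code{"log"}. Vertices not named default to
#'   \code{"identity"}.
#'
#' @return An object of class \code{"causal_model"} with components
#'   \code{name}, \code{vertices}, \code{edges} (two-column character
#'   matrix), \code{family}, \code{transform}.
#'
#' @examples
#' m <- causal_model("chain", c("A", "B", "C"),
#'                   list(c("A", "B"), c("B", "C")))
#' topological_order(m)
#' @export
causal_model <- function(name, vertices, edges = list(),
                         family = NULL, transform = NULL) {
  stopifnot(is.character(vertices), length(vertices) >= 1)
  if (anyDuplicated(vertices))
    stop("duplicate vertex names: ",
         paste(unique(vertices[duplicated(vertices)]), collapse = ", "))
  if (is.matrix(edges)) {
    edges <- lapply(seq_len(nrow(edges)), function(i) as.character(edges[i, ]))
  }
  em <- if (length(edges) == 0) {
    matrix(character(0), ncol = 2, dimnames = list(NULL, c("parent", "child")))
  } else {
    do.call(rbind, lapply(edges, function(e) {
      if (length(e) != 2) stop("each edge must be a pair c(parent, child)")
      matrix(as.character(e), ncol = 2)
    }))
  }
  colnames(em) <- c("parent", "child")
  unknown <- setdiff(c(em), vertices)
  if (length(unknown))
    stop("edge endpoints not among the vertices: ",
         paste(unknown, collapse = ", "))
  if (any(em[, 1] == em[, 2]))
    stop("self-loop on vertex: ", em[em[, 1] == em[, 2], 1][1])
  key <- paste(em[, 1], em[, 2], sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate edge: ", gsub("\r", " -> ", key[duplicated(key)][1]))

  fam <- rep("gaussian", length(vertices)); names(fam) <- vertices
  if (!is.null(family)) {
    bad <- setdiff(family, c("gaussian", "poisson", "gamma"))
    if (length(bad)) stop("unknown family: ", paste(bad, collapse = ", "))
    fam[names(family)] <- family
  }
  trf <- rep("identity", length(vertices)); names(trf) <- vertices
  if (!is.null(transform)) {
    bad <- setdiff(transform, c("identity", "log"))
    if (length(bad)) stop("unknown transform: ", paste(bad, collapse = ", "))
    trf[names(transform)] <- transform
  }

  m <- structure(list(name = name, vertices = vertices, edges = em,
                      family = fam, transform = trf),
                 class = "causal_model")
  validate_model(m)   # errors on cycles
  m
}

#' Validate a causal model
#'
#' Checks well-formedness and acyclicity. On success the topological order
#' is returned invisibly; a cycle raises an error listing the vertices that
#' remain entangled in it.
#'
#' @param model A \code{"causal_model"}.
#' @return Invisibly, the topological order of the vertices.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "causal_model"))
  invisible(topological_order(model))
}

#' Topological order of a causal model
#'
#' Kahn's algorithm with the declared vertex order as tie-break, so the
#' result is deterministic for a given model.
#'
#' @param model A \code{"causal_model"}.
#' @return Character vector: the vertices in topological order.
#' @export
topological_order <- function(model) {
  v <- model$vertices
  indeg <- stats::setNames(integer(length(v)), v)
  tab <- table(factor(model$edges[, "child"], levels = v))
  indeg[names(tab)] <- as.integer(tab)
  out <- character(0)
  remaining <- v
  while (length(remaining)) {
    ready <- remaining[indeg[remaining] == 0]
    if (!length(ready))
      stop("model '", model$name, "' contains a cycle among: ",
           paste(remaining, collapse = ", "))
    nxt <- ready[1]                      # declared order breaks ties
    out <- c(out, nxt)
    remaining <- setdiff(remaining, nxt)
    ch <- model$edges[model$edges[, "parent"] == nxt, "child"]
    indeg[ch] <- indeg[ch] - 1L
  }
  out
}

#' Parents of a vertex
#' @param model A \code{"causal_model"}.
#' @param vertex Vertex name.
#' @return Character vector of parent vertices (possibly empty).
#' @export
parents <- function(model, vertex) {
  if (!vertex %in% model$vertices) stop("unknown vertex: ", vertex)
  unname(model$edges[model$edges[, "child"] == vertex, "parent"])
}

children_of <- function(model, vertex) {
  unname(model$edges[model$edges[, "parent"] == vertex, "child"])
}

#' Child vertices (those with at least one parent)
#' @param model A \code{"causal_model"}.
#' @return Character vector of vertices that appear as a child of some edge.
#' @export
child_vertices <- function(model) {
  intersect(topological_order(model), unique(model$edges[, "child"]))
}

adjacent <- function(model, x, y) {
  any((model$edges[, 1] == x & model$edges[, 2] == y) |
      (model$edges[, 1] == y & model$edges[, 2] == x))
}

ancestors_of <- function(model, vertices) {
  # reflexive transitive closure over parent links
  seen <- character(0)
  frontier <- vertices
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(
      unique(unlist(lapply(frontier, parents, model = model))), seen)
  }
  seen
}

#' Test d-separation in a causal model
#'
#' Decides whether \code{x} and \code{y} are d-separated given the
#' conditioning set \code{z}, by reachability on the moralized ancestral
#' subgraph: restrict the DAG to the ancestors of \code{x}, \code{y} and
#' \code{z}; marry all parents sharing a child; drop edge directions; delete
#' \code{z}; then \code{x} and \code{y} are d-separated iff they are
#' disconnected.
#'
#' @param model A \code{"causal_model"}.
#' @param x,y Vertex names, distinct.
#' @param z Character vector of conditioning vertices (may be empty).
#' @return Logical scalar.
#' @examples
#' m <- causal_model("collider", c("X", "Y", "Z"),
#'                   list(c("X", "Z"), c("Y", "Z")))
#' d_separated(m, "X", "Y", character(0))  # TRUE
#' d_separated(m, "X", "Y", "Z")           # FALSE
#' @export
d_separated <- function(model, x, y, z = character(0)) {
  z <- as.character(z)
  miss <- setdiff(c(x, y, z), model$vertices)
  if (length(miss)) stop("unknown vertex: ", paste(miss, collapse = ", "))
  if (x == y) stop("x and y must differ")
  if (x %in% z || y %in% z) stop("conditioning set must exclude x and y")

  anc <- ancestors_of(model, c(x, y, z))
  sub <- model$edges[model$edges[, 1] %in% anc & model$edges[, 2] %in% anc, ,
                     drop = FALSE]
  # undirected adjacency of the moral graph on `anc`
  nb <- stats::setNames(vector("list", length(anc)), anc)
  add <- function(a, b) {
    nb[[a]] <<- union(nb[[a]], b)
    nb[[b]] <<- union(nb[[b]], a)
  }
  for (i in seq_len(nrow(sub))) add(sub[i, 1], sub[i, 2])
  for (ch in unique(sub[, 2])) {            # marry co-parents
    pa <- sub[sub[, 2] == ch, 1]
    if (length(pa) > 1) {
      cmb <- utils::combn(pa, 2)
      for (j in seq_len(ncol(cmb))) add(cmb[1, j], cmb[2, j])
    }
  }
  # BFS from x avoiding z
  visited <- x
  frontier <- x
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(nb[frontier])), c(visited, z))
    if (y %in% nxt) return(FALSE)
    visited <- c(visited, nxt)
    frontier <- nxt
  }
  TRUE
}

#' Shipley basis set of independence claims
#'
#' One claim per non-adjacent unordered vertex pair, conditioned on the
#' union of the parents of both vertices. The claim's designated response
#' (used by the regression claim-testing engine) is the pair member that
#' comes later in topological order. Every returned claim is d-separated in
#' the model, and the number of claims equals
#' \code{choose(length(vertices), 2) - nrow(edges)}.
#'
#' @param model A \code{"causal_model"}.
#' @return A list of claims of class \code{"independence_claim"}, each with
#'   components \code{x}, \code{y}, \code{given}, \code{response}.
#' @examples
#' m <- truffle_models()$single_A
#' length(basis_set(m))   # 7 claims, so the Fisher's C test has 14 df
#' @export
basis_set <- function(model) {
  ord <- topological_order(model)
  v <- ord
  claims <- list()
  if (length(v) >= 2) {
    cmb <- utils::combn(v, 2)
    for (j in seq_len(ncol(cmb))) {
      a <- cmb[1, j]; b <- cmb[2, j]      # a earlier in topological order
      if (adjacent(model, a, b)) next
      cond <- setdiff(union(parents(model, a), parents(model, b)), c(a, b))
      claim <- structure(
        list(x = a, y = b, given = sort(cond), response = b),
        class = "independence_claim")
      if (!d_separated(model, a, b, cond))
        stop("internal error: basis claim not d-separated: ", a, " _||_ ", b)
      claims[[length(claims) + 1]] <- claim
    }
  }
  expected <- choose(length(v), 2) - nrow(model$edges)
  if (length(claims) != expected)
    stop("internal error: basis set size ", length(claims),
         " != C(|V|,2) - |E| = ", expected)
  claims
}

#' @export
print.independence_claim <- function(x, ...) {
  cond <- if (length(x$given)) paste(x$given, collapse = ", ") else "{}"
  cat(x$x, "_||_", x$y, "|", cond, "\n")
  invisible(x)
}

#' @export
print.causal_model <- function(x, ...) {
  cat("Causal model '", x$name, "': ", length(x$vertices), " vertices, ",
      nrow(x$edges), " edges\n", sep = "")
  if (nrow(x$edges))
    cat(paste0("  ", x$edges[, 1], " -> ", x$edges[, 2]), sep = "\n")
  k <- choose(length(x$vertices), 2) - nrow(x$edges)
  cat("Basis set: ", k, " claims (Fisher's C on ", 2 * k, " df)\n", sep = "")
  invisible(x)
}

#' Read / write causal models as JSON
#'
#' The document has fields \code{name}, \code{vertices}, \code{edges} (an
#' array of \code{[parent, child]} pairs), \code{family} and
#' \code{transform} (objects keyed by vertex).
#'
#' @param path File path.
#' @return \code{read_model}: a \code{"causal_model"}.
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- doc$edges
  if (is.matrix(edges)) edges <- lapply(seq_len(nrow(edges)),
                                        function(i) edges[i, ])
  causal_model(doc$name, doc$vertices, edges,
               family = unlist(doc$family), transform = unlist(doc$transform))
}

#' @param model A \code{"causal_model"}.
#' @rdname read_model
#' @export
write_model <- function(model, path) {
  doc <- list(
    name = model$name,
    vertices = model$vertices,
    edges = lapply(seq_len(nrow(model$edges)),
                   function(i) unname(model$edges[i, ])),
    family = as.list(model$family),
    transform = as.list(model$transform))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Export a causal model in DOT format for visualization
#' @param model A \code{"causal_model"}.
#' @param path Optional file; if missing the DOT source is returned.
#' @return The DOT source, invisibly if written to file.
#' @export
model_to_dot <- function(model, path = NULL) {
  lines <- c(sprintf("digraph \"%s\" {", model$name),
             sprintf("  \"%s\";", model$vertices),
             sprintf("  \"%s\" -> \"%s\";",
                     model$edges[, 1], model$edges[, 2]),
             "}")
  src <- paste(lines, collapse = "\n")
  if (is.null(path)) return(src)
  writeLines(src, path)
  invisible(src)
}
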