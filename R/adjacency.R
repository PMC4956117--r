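#' Region adjacency graphs
#'
#' An `adjacency_graph` holds the undirected neighbourhood structure of the
#' study regions: unique integer region ids, an edge list, optional display
#' names, and the connected-component label of every node.  It is the input
#' to the intrinsic CAR (Markov random field) prior on the structured
#' spatial effect.
#'
#' @param edges two-column integer matrix or data.frame of undirected edges
#'   (region ids).  Self-loops are rejected; duplicate or reversed edges are
#'   collapsed.
#' @param ids integer vector of all region ids (defaults to the ids present
#'   in `edges`; pass explicitly to keep isolated regions).
#' @param names optional character vector of region names, parallel to `ids`.
#' @return An object of class `adjacency_graph` with elements `ids`, `names`,
#'   `edges` (m x 2 integer matrix, smaller id first), `component` (integer
#'   label per id) and `n`.
#' @export
adjacency_graph <- function(edges, ids = NULL, names = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) edges <- matrix(integer(), ncol = 2L)
  if (ncol(edges) != 2L) stop("edges must have two columns")
  storage.mode(edges) <- "integer"
  if (anyNA(edges)) stop("edges contain missing ids")
  if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
  if (is.null(ids)) ids <- sort(unique(as.vector(edges)))
  ids <- sort(unique(as.integer(ids)))
  if (length(ids) == 0L) stop("empty graph: no region ids")
  if (!all(as.vector(edges) %in% ids)) stop("edge refers to an unknown region id")
  if (!is.null(names)) {
    if (length(names) != length(ids)) stop("names must be parallel to ids")
    names <- as.character(names)
  }
  # canonical order: smaller id first, dedupe
  e <- cbind(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  e <- unique(e[order(e[, 1L], e[, 2L]), , drop = FALSE])
  g <- structure(list(ids = ids, names = names, edges = e, n = length(ids)),
                 class = "adjacency_graph")
  g$component <- graph_components(g)
  g
}

#' Connected components of an adjacency graph
#'
#' Label propagation on the edge list; O(n * m), plenty for region graphs.
#'
#' @param graph an `adjacency_graph` (the `component` field may be absent).
#' @return Integer vector of component labels (1-based), parallel to
#'   `graph$ids`.
#' @export
graph_components <- function(graph) {
  n <- graph$n
  idx <- match(graph$edges, graph$ids)
  e <- matrix(idx, ncol = 2L)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(e))) {
      a <- comp[e[r, 1L]]; b <- comp[e[r, 2L]]
      if (a != b) {
        comp[comp == max(a, b)] <- min(a, b)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, sort(unique(comp)))
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat("<adjacency_graph>", x$n, "regions,", nrow(x$edges), "edges,",
      max(x$component), "component(s)\n")
  invisible(x)
}

#' Read an adjacency graph from a plain-text edge list
#'
#' One undirected edge per line, "region_a region_b"; lines starting with
#' `#` are comments.  An optional lookup CSV supplies ids and names (and
#' keeps isolated regions in the graph).
#'
#' @param path edge-list file.
#' @param lookup optional CSV with columns `region_id` and `name`.
#' @return An `adjacency_graph`.
#' @export
read_adjacency <- function(path, lookup = NULL) {
  if (!file.exists(path)) stop("adjacency file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("adjacency file has no edges: ", path)
  parts <- strsplit(lines, "[[:space:]]+")
  if (any(lengths(parts) != 2L)) stop("malformed edge line in ", path)
  e <- matrix(as.integer(unlist(parts)), ncol = 2L, byrow = TRUE)
  ids <- NULL; nms <- NULL
  if (!is.null(lookup)) {
    tab <- utils::read.csv(lookup, stringsAsFactors = FALSE)
    if (!all(c("region_id", "name") %in% names(tab)))
      stop("lookup must have columns region_id and name")
    ord <- order(tab$region_id)
    ids <- tab$region_id[ord]; nms <- tab$name[ord]
  }
  adjacency_graph(e, ids = ids, names = nms)
}

#' The bundled Egypt governorate graph
#'
#' A curated first-order adjacency of Egypt's 27 governorates (ids 1..27
#' with names and EDHS area classes), shipped as a documented plain-text
#' fixture.  The source survey provides no digital adjacency, so this graph
#' was hand-curated from public administrative geography; substitute your
#' own edge list via [read_adjacency()] if a different neighbourhood
#' definition is preferred -- every fitted result records which graph was
#' used.
#'
#' @return An `adjacency_graph` with 27 regions in a single component and an
#'   `area_class` attribute (governorate-level class used to derive the
#'   EDHS seven-way area split together with urban/rural residence).
#' @export
egypt_graph <- function() {
  edge_file <- system.file("extdata", "egypt_adjacency.txt",
                           package = "morbidmap", mustWork = TRUE)
  lookup <- system.file("extdata", "egypt_governorates.csv",
                        package = "morbidmap", mustWork = TRUE)
  g <- read_adjacency(edge_file, lookup)
  tab <- utils::read.csv(lookup, stringsAsFactors = FALSE)
  attr(g, "area_class") <- stats::setNames(tab$area_class, tab$region_id)
  g
}

#' Intrinsic CAR precision matrix from an adjacency graph
#'
#' Builds `Q = D - A` (degree matrix minus adjacency), the graph Laplacian
#' that scales the improper Gaussian Markov-random-field prior on the
#' structured spatial effect.  Every row of `Q` sums to zero; `Q` is
#' positive semidefinite with rank `n - n_components`.
#'
#' @param graph an `adjacency_graph`.
#' @return An `icar_precision`: the matrix `Q` with attributes `ids`,
#'   `rank` and `n_components`.
#' @export
build_icar_precision <- function(graph) {
  stopifnot(inherits(graph, "adjacency_graph"))
  n <- graph$n
  Q <- matrix(0, n, n, dimnames = list(graph$ids, graph$ids))
  idx <- matrix(match(graph$edges, graph$ids), ncol = 2L)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1L]; j <- idx[r, 2L]
    Q[i, j] <- Q[i, j] - 1
    Q[j, i] <- Q[j, i] - 1
    Q[i, i] <- Q[i, i] + 1
    Q[j, j] <- Q[j, j] + 1
  }
  iso <- which(diag(Q) == 0)
  if (length(iso))
    warning("isolated region(s) ", paste(graph$ids[iso], collapse = ", "),
            ": structured effect unidentified there (handled by constraint)")
  ncomp <- max(graph$component)
  structure(Q, ids = graph$ids, rank = n - ncomp, n_components = ncomp,
            class = c("icar_precision", "matrix", "array"))
}
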