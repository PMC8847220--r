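#' Layered nearest-neighbor natural graph
#'
#' The natural graph visualizes relationships between units (populations) in
#' layers. Layer 1 links every unit to its closest other unit; the weakly
#' connected components of these links are the groups. Layer 2 links every
#' group to its nearest other group, and so on, until a single component
#' remains or `layers` is reached. Two layers are usually enough.
#'
#' Group-to-group distance is single linkage (minimum member pair distance)
#' by default, matching the closest-neighbor spirit of the construction;
#' `"mean"` linkage is available. Ties in nearest neighbors are broken toward
#' the lexicographically smallest label, so the output is deterministic.
#'
#' @param m A labeled distance matrix over at least 2 units.
#' @param layers Maximum number of layers to build (default 2).
#' @param group_distance `"min"` (single linkage, default) or `"mean"`.
#' @return An object of class `natural_graph`: a list with `units`, `edges`
#'   (tibble: `layer`, `from`, `to`, `distance`), and `membership` (tibble:
#'   `unit`, `group`, the layer-1 group of each unit, with further columns
#'   `group_l<j>` for deeper layers when built).
#' @export
build_natural_graph <- function(m, layers = 2, group_distance = c("min", "mean")) {
  group_distance <- match.arg(group_distance)
  m <- validate_labeled_matrix(unclass(m))
  if (nrow(m) < 2) abort("need at least 2 units")
  stopifnot(layers >= 1)

  units <- rownames(m)
  membership <- tibble(unit = units)
  edges <- list()

  # current partition: list of character vectors of unit labels
  current <- as.list(units)
  names(current) <- units
  layer <- 0L
  repeat {
    layer <- layer + 1L
    if (layer > layers || length(current) < 2) break
    dmat <- group_distance_matrix(m, current, group_distance)
    e <- nearest_neighbor_edges(dmat, layer)
    edges[[layer]] <- e
    comp <- connected_groups(names(current), e)
    # merge members; name each group by its lexicographically first member
    merged <- lapply(comp, function(g) sort(unlist(current[g], use.names = FALSE)))
    names(merged) <- vapply(comp, function(g) min(g), character(1))
    col <- if (layer == 1) "group" else paste0("group_l", layer)
    membership[[col]] <- vapply(membership$unit, function(u) {
      names(merged)[vapply(merged, function(g) u %in% g, logical(1))][1]
    }, character(1))
    if (length(merged) == length(current)) break  # no further coalescence
    current <- merged
  }

  structure(
    list(units = units,
         edges = dplyr::bind_rows(edges),
         membership = membership),
    class = "natural_graph")
}

group_distance_matrix <- function(m, groups, method) {
  k <- length(groups)
  labs <- names(groups)
  out <- matrix(0, k, k, dimnames = list(labs, labs))
  if (k < 2) return(out)
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) {
      block <- m[groups[[i]], groups[[j]], drop = FALSE]
      d <- if (method == "min") min(block) else mean(block)
      out[i, j] <- d
      out[j, i] <- d
    }
  }
  out
}

# Each unit points at its minimum-distance other unit; ties go to the
# lexicographically smallest label.
nearest_neighbor_edges <- function(dmat, layer) {
  labs <- rownames(dmat)
  ord_labs <- order(labs)
  to <- character(length(labs))
  dd <- numeric(length(labs))
  for (i in seq_along(labs)) {
    cand <- setdiff(ord_labs, i)
    d <- dmat[i, cand]
    best <- cand[which.min(d)]  # cand is in label order, so ties pick smallest
    to[i] <- labs[best]
    dd[i] <- dmat[i, best]
  }
  tibble(layer = layer, from = labs, to = to, distance = dd)
}

connected_groups <- function(labs, edges) {
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = labs))
  comp <- igraph::components(g)
  split(labs, comp$membership[labs])
}

#' @export
print.natural_graph <- function(x, ...) {
  n_groups <- length(unique(x$membership$group))
  cat("Natural graph:", length(x$units), "units,",
      n_groups, "layer-1 group(s),",
      max(x$edges$layer), "layer(s)\n")
  print(x$edges, n = 20)
  invisible(x)
}

#' Tidy the edge list of a natural graph
#'
#' @param x A `natural_graph`.
#' @param ... Unused.
#' @return The edge tibble (`layer`, `from`, `to`, `distance`).
#' @export
tidy.natural_graph <- function(x, ...) {
  x$edges
}

#' One-row summary of a natural graph
#'
#' @param x A `natural_graph`.
#' @param ... Unused.
#' @return A tibble with `n_units`, `n_groups`, `n_layers`, `n_edges`.
#' @export
glance.natural_graph <- function(x, ...) {
  tibble(n_units = length(x$units),
         n_groups = length(unique(x$membership$group)),
         n_layers = max(x$edges$layer),
         n_edges = nrow(x$edges))
}

#' Plot a natural graph
#'
#' Layer-1 edges are drawn thin, higher layers thick; layout is
#' force-directed (Fruchterman–Reingold) on the layer-1 links.
#'
#' @param object A `natural_graph`.
#' @param seed Layout seed for reproducible coordinates.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.natural_graph <- function(object, seed = 42, ...) {
  g <- igraph::graph_from_data_frame(
    object$edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = object$units))
  xy <- withr_seed_layout(g, seed)
  nodes <- tibble(name = object$units, x = xy[, 1], y = xy[, 2])
  ed <- dplyr::left_join(object$edges,
                         setNames(nodes, c("from", "x0", "y0")), by = "from")
  ed <- dplyr::left_join(ed, setNames(nodes, c("to", "x1", "y1")), by = "to")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, linewidth = factor(.data$layer),
                   colour = factor(.data$layer))) +
    ggplot2::geom_label(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     label = .data$name), size = 3) +
    ggplot2::scale_linewidth_manual(values = c(`1` = 0.4, `2` = 1.2, `3` = 2)) +
    ggplot2::labs(colour = "layer", linewidth = "layer") +
    ggplot2::theme_void()
}

withr_seed_layout <- function(g, seed) {
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  igraph::layout_with_fr(g)
}

#' Write a natural graph as DOT and TSV edge list
#'
#' @param graph A `natural_graph`.
#' @param dot_path Optional path for a Graphviz DOT rendering of the edges.
#' @param tsv_path Optional path for the layer-annotated edge list.
#' @return The graph, invisibly.
#' @export
write_natural_graph <- function(graph, dot_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(graph, "natural_graph"))
  if (!is.null(tsv_path)) {
    readr::write_tsv(graph$edges, tsv_path)
  }
  if (!is.null(dot_path)) {
    lines <- c("graph natural_graph {",
               sprintf("  \"%s\" -- \"%s\" [label=\"L%d\", penwidth=%d];",
                       graph$edges$from, graph$edges$to, graph$edges$layer,
                       graph$edges$layer),
               "}")
    writeLines(lines, dot_path)
  }
  invisible(graph)
}
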