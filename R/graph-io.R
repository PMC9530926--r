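#' Convert an association graph to an igraph object
#'
#' @param graph An `association_graph`.
#' @return An undirected igraph with vertex attributes and edge
#'   `distance`/`weight`.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "association_graph"))
  if (nrow(graph$edges) == 0L) abort("empty graph")
  dup <- graph$vertices$name[duplicated(graph$vertices$name)]
  if (length(dup) > 0L) {
    abort(sprintf("duplicate vertex name(s): %s",
                  paste(unique(dup), collapse = ", ")))
  }
  verts <- graph$vertices
  for (col in names(verts)) {
    if (is.character(verts[[col]])) {
      verts[[col]][is.na(verts[[col]])] <- ""
    }
  }
  g <- igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                     vertices = verts)
  igraph::E(g)$weight <- igraph::E(g)$distance
  g
}

#' Export / import an association graph
#'
#' Writes the MST-filtered association graph with vertex annotations
#' (provenance tag, `Max_`/`Min_` kind) and edge distances, in GraphML
#' (round-trippable via [import_graph()]) or DOT format, chosen from the
#' file extension.
#'
#' @param graph An `association_graph`.
#' @param path Output file, extension `.graphml` or `.dot`/`.gv`.
#' @return `export_graph()` the path invisibly; `import_graph()` an
#'   `association_graph`.
#' @export
export_graph <- function(graph, path) {
  g <- as_igraph(graph)
  ext <- tolower(tools::file_ext(path))
  fmt <- switch(ext,
    graphml = "graphml",
    dot = "dot", gv = "dot",
    abort(sprintf("unsupported graph format: .%s (use .graphml or .dot)", ext))
  )
  igraph::write_graph(g, path, format = fmt)
  invisible(path)
}

#' @rdname export_graph
#' @export
import_graph <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  verts <- igraph::as_data_frame(g, what = "vertices")
  edges <- igraph::as_data_frame(g, what = "edges")
  vertices <- as_tibble(verts) %>% rename(name = "name")
  keep <- setdiff(names(vertices), "id")
  structure(
    list(
      vertices = vertices[keep],
      edges = tibble(from = edges$from, to = edges$to,
                     distance = edges$distance),
      total_distance = sum(edges$distance)
    ),
    class = "association_graph"
  )
}

#' Plot an association graph
#'
#' Fruchterman--Reingold layout (deterministic: seeded internally) with
#' vertices coloured by provenance tag and shaped by `Max_`/`Min_` kind.
#'
#' @param object An `association_graph`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @export
autoplot.association_graph <- function(object, seed = 42L, ...) {
  g <- as_igraph(object)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  verts <- object$vertices %>%
    mutate(x = xy[, 1], y = xy[, 2])
  edges <- object$edges %>%
    left_join(verts[c("name", "x", "y")], by = c(from = "name")) %>%
    rename(x0 = "x", y0 = "y") %>%
    left_join(verts[c("name", "x", "y")], by = c(to = "name"))
  has_prov <- "provenance" %in% names(verts)
  pl <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges, colour = "grey50",
      ggplot2::aes(x = .data$x0, y = .data$y0,
                   xend = .data$x, yend = .data$y)
    )
  if (has_prov) {
    pl <- pl + ggplot2::geom_point(
      data = verts, size = 2.5,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$provenance)
    )
  } else {
    pl <- pl + ggplot2::geom_point(
      data = verts, size = 2.5,
      ggplot2::aes(x = .data$x, y = .data$y)
    )
  }
  pl +
    ggplot2::geom_text(
      data = verts, size = 2.2, vjust = -0.8,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$name)
    ) +
    ggplot2::theme_void()
}
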