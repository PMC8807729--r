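## Multi-layer network container and serialization (GraphML, TSV edge list).

#' Construct a multi-layer network
#'
#' Typed nodes (metal, isotope, phenotype, feature_set) and provenance-tagged
#' weighted signed edges, as drawn in integrated metallome network figures.
#'
#' @param nodes Tibble with columns `id` (unique) and `type` in
#'   `c("metal", "isotope", "phenotype", "feature_set")`.
#' @param edges Tibble with columns `from`, `to`, `weight`, `sign`, `adj_p`,
#'   `layer` and optionally `organ`.
#' @return An object of class `multilayer_network`.
#' @export
multilayer_network <- function(nodes = tibble::tibble(id = character(), type = character()),
                               edges = empty_edges()) {
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  if (!"organ" %in% names(edges)) edges$organ <- rep(NA_character_, nrow(edges))
  net <- structure(list(nodes = nodes, edges = edges), class = "multilayer_network")
  validate_network(net)
}

empty_edges <- function() {
  tibble::tibble(
    from = character(), to = character(), weight = double(),
    sign = double(), adj_p = double(), layer = character(),
    organ = character()
  )
}

#' @export
print.multilayer_network <- function(x, ...) {
  cat(
    "<multilayer_network> ", nrow(x$nodes), " nodes, ",
    nrow(x$edges), " edges\n",
    sep = ""
  )
  if (nrow(x$edges) > 0) print(dplyr::count(x$edges, .data$layer))
  invisible(x)
}

validate_network <- function(net) {
  nodes <- net$nodes
  edges <- net$edges
  if (anyDuplicated(nodes$id) > 0) {
    abort("duplicate node id", class = "metalloscope_schema_error")
  }
  bad_type <- setdiff(unique(nodes$type), c("metal", "isotope", "phenotype", "feature_set"))
  if (length(bad_type) > 0) {
    abort(paste0("unknown node type: ", paste(bad_type, collapse = ", ")),
      class = "metalloscope_schema_error"
    )
  }
  if (nrow(edges) > 0) {
    dangling <- setdiff(c(edges$from, edges$to), nodes$id)
    if (length(dangling) > 0) {
      abort(paste0("edge endpoint not in node set: ", paste(head(dangling, 5), collapse = ", ")),
        class = "metalloscope_schema_error"
      )
    }
    if (any(edges$from == edges$to)) {
      abort("self-edges are not allowed", class = "metalloscope_schema_error")
    }
    key <- edge_key(edges)
    if (anyDuplicated(key) > 0) {
      abort(paste0(
        "duplicate edge key: ",
        paste(head(unique(key[duplicated(key)]), 3), collapse = "; ")
      ), class = "metalloscope_schema_error")
    }
  }
  net
}

# undirected edge identity within a layer (and organ family)
edge_key <- function(edges) {
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  paste(a, b, edges$layer, ifelse(is.na(edges$organ), "", edges$organ), sep = "|")
}

#' Write a multi-layer network to disk
#'
#' `edge_tsv` writes the edge table to `path` and the node table to a
#' companion file (`*_nodes.tsv`), so that isolated nodes survive the
#' round trip. `graphml` writes a single GraphML file with typed node and
#' edge attributes via igraph.
#'
#' @param net A `multilayer_network`.
#' @param path Output path.
#' @param format `"graphml"` or `"edge_tsv"`.
#' @return `path`, invisibly.
#' @seealso [read_network()]
#' @export
write_network <- function(net, path, format = c("graphml", "edge_tsv")) {
  format <- match.arg(format)
  validate_network(net)
  if (format == "edge_tsv") {
    readr::write_tsv(net$edges, path, na = "NA")
    readr::write_tsv(net$nodes, nodes_companion_path(path), na = "NA")
  } else {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

nodes_companion_path <- function(path) {
  sub("(\\.[A-Za-z0-9]+)?$", "_nodes.tsv", path)
}

#' Convert a multi-layer network to an igraph graph
#' @param net A `multilayer_network`.
#' @return An undirected `igraph` graph with node/edge attributes.
#' @export
as_igraph <- function(net) {
  edges <- net$edges
  # GraphML has no missing-value notion for string attributes
  edges$organ[is.na(edges$organ)] <- ""
  igraph::graph_from_data_frame(
    d = edges, directed = FALSE,
    vertices = as.data.frame(net$nodes)
  )
}

#' Read a multi-layer network written by [write_network()]
#'
#' @param path File path.
#' @param format `"graphml"` or `"edge_tsv"`.
#' @return A `multilayer_network`.
#' @export
read_network <- function(path, format = c("graphml", "edge_tsv")) {
  format <- match.arg(format)
  if (format == "edge_tsv") {
    edges <- readr::read_tsv(path,
      show_col_types = FALSE, progress = FALSE,
      col_types = readr::cols(
        from = "c", to = "c", weight = "d", sign = "d",
        adj_p = "d", layer = "c", organ = "c"
      )
    )
    nodes <- readr::read_tsv(nodes_companion_path(path),
      show_col_types = FALSE, progress = FALSE,
      col_types = readr::cols(id = "c", type = "c")
    )
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    if (igraph::vcount(g) == 0) {
      return(multilayer_network())
    }
    nodes <- tibble::tibble(
      id = igraph::vertex_attr(g, "name"),
      type = igraph::vertex_attr(g, "type")
    )
    ea <- igraph::as_data_frame(g, what = "edges")
    edges <- tibble::as_tibble(ea)
    if (nrow(edges) == 0) {
      edges <- empty_edges()
    } else {
      names(edges)[1:2] <- c("from", "to")
      edges$organ[edges$organ == ""] <- NA_character_
    }
  }
  multilayer_network(nodes, edges)
}
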