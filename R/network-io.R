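#' Read and write networks
#'
#' Networks travel either as GraphML (via igraph, preserving all attributes)
#' or as a plain edge-list TSV with columns `from` and `to`. In the TSV form
#' an isolated node is written as a row whose `to` field is empty, so that
#' node sets always round-trip exactly.
#'
#' @param net An igraph graph. Vertices should be named.
#' @param path Output path.
#' @param format `"tsv"` (edge list) or `"graphml"`. For [read_network()]
#'   the default `NULL` guesses from the file extension.
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   returns an igraph graph.
#' @export
write_network <- function(net, path, format = c("tsv", "graphml")) {
  stopifnot(igraph::is_igraph(net))
  format <- match.arg(format)
  if (is.null(igraph::V(net)$name)) {
    igraph::V(net)$name <- as.character(seq_len(igraph::vcount(net)))
  }
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
    return(invisible(path))
  }
  el <- igraph::as_edgelist(net, names = TRUE)
  iso <- setdiff(igraph::V(net)$name, unique(as.vector(el)))
  df <- tibble::tibble(
    from = c(el[, 1], iso),
    to = c(el[, 2], rep(NA_character_, length(iso)))
  )
  readr::write_tsv(df, path, col_names = TRUE, na = "")
  invisible(path)
}

#' @rdname write_network
#' @param directed For TSV input, whether to build a directed graph
#'   (default TRUE). GraphML stores directedness itself.
#' @export
read_network <- function(path, format = NULL, directed = TRUE) {
  if (is.null(format)) {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml" else "tsv"
  }
  if (!format %in% c("tsv", "graphml")) {
    stop("unknown network format: ", format, call. = FALSE)
  }
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    return(g)
  }
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        na = "", progress = FALSE)
  if (!all(c("from", "to") %in% names(df))) {
    stop("edge-list TSV must have columns `from` and `to`", call. = FALSE)
  }
  edges <- df[!is.na(df$to), , drop = FALSE]
  nodes <- unique(c(df$from, edges$to))
  igraph::graph_from_data_frame(edges, directed = directed,
                                vertices = data.frame(name = nodes))
}
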