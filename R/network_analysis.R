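EVIDENCE_CHANNELS <- c("coexpression", "experiments", "database", "textmining",
                       "neighborhood", "fusion", "cooccurrence")

#' Construct an undirected gene interaction graph
#'
#' Wraps a weighted, evidence-typed protein/gene association network of the
#' kind exported by STRING. Edges are unordered pairs with a `combined_score`
#' in \[0, 1\] and optional per-channel evidence scores (coexpression,
#' experiments, database, textmining, neighborhood, fusion, cooccurrence).
#' Self-loops are dropped; duplicate pairs (in either orientation) are merged
#' keeping the elementwise maximum of their scores.
#'
#' @param edges Data frame with two endpoint columns named `from` and `to`
#'   (or the first two columns), a `combined_score` column, and optionally
#'   per-channel score columns. May have zero rows.
#' @param nodes Character vector of node names to include even if they have
#'   no edges.
#' @return An object of class `interaction_graph`.
#' @export
interaction_graph <- function(edges = NULL, nodes = character()) {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- tibble::tibble(from = character(), to = character(),
                            combined_score = numeric())
  }
  edges <- tibble::as_tibble(edges)
  if (!all(c("from", "to") %in% names(edges))) {
    names(edges)[1:2] <- c("from", "to")
  }
  if (!("combined_score" %in% names(edges))) {
    stop_enorthern("edge table must have a combined_score column",
                   "enorthern_parse_error")
  }
  score_cols <- intersect(c("combined_score", EVIDENCE_CHANNELS), names(edges))
  for (col in score_cols) {
    x <- edges[[col]]
    if (!is.numeric(x) || any(!is.na(x) & (x < 0 | x > 1))) {
      stop_enorthern(paste0("scores in '", col, "' must lie in [0, 1]"),
                     "enorthern_validation_error")
    }
  }
  edges <- edges[c("from", "to", setdiff(score_cols, c("from", "to")))]
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  # canonical orientation, then elementwise max over duplicates
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  edges$from <- a
  edges$to <- b
  if (nrow(edges) > 0) {
    edges <- dplyr::summarise(
      dplyr::group_by(edges, .data$from, .data$to),
      dplyr::across(dplyr::everything(), ~ suppressWarnings(max(.x, na.rm = TRUE))),
      .groups = "drop"
    )
    for (col in score_cols) {
      edges[[col]][!is.finite(edges[[col]])] <- NA_real_
    }
  }
  all_nodes <- sort(unique(c(nodes, edges$from, edges$to)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = all_nodes)
  structure(list(graph = g, channels = setdiff(score_cols, "combined_score")),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat("<interaction_graph> ", igraph::vcount(x$graph), " nodes, ",
      igraph::ecount(x$graph), " edges",
      if (length(x$channels)) paste0("; channels: ", paste(x$channels, collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

#' Node names of an interaction graph
#' @param graph An [interaction_graph()].
#' @return Character vector of node names.
#' @export
graph_nodes <- function(graph) {
  stopifnot(inherits(graph, "interaction_graph"))
  igraph::V(graph$graph)$name
}

#' Edge table of an interaction graph
#' @param graph An [interaction_graph()].
#' @return Tibble with columns `from`, `to`, `combined_score` and any
#'   per-channel scores.
#' @export
graph_edges <- function(graph) {
  stopifnot(inherits(graph, "interaction_graph"))
  tibble::as_tibble(igraph::as_data_frame(graph$graph, what = "edges"))
}

#' Read a STRING-style weighted edge list
#'
#' Parses a tab-separated edge list with a header naming two node columns
#' (`protein1`/`protein2`, `node1`/`node2`, `from`/`to`, or simply the first
#' two columns) and at least `combined_score`; per-channel evidence columns
#' are picked up when present. Scores must lie in \[0, 1\]. Reversed
#' duplicate rows are merged keeping the maximum score, matching STRING's
#' symmetric export convention.
#'
#' @param path Path to the TSV file.
#' @param nodes Optional character vector of additional node names to keep
#'   as isolated nodes (e.g. panel genes with no interactions).
#' @return An [interaction_graph()].
#' @export
read_edge_list <- function(path, nodes = character()) {
  if (!file.exists(path)) {
    stop_enorthern(paste0("file not found: ", path), "enorthern_io_error")
  }
  raw <- readr::read_tsv(path, comment = "#", progress = FALSE,
                         show_col_types = FALSE)
  endpoint_names <- list(c("protein1", "protein2"), c("node1", "node2"),
                         c("gene1", "gene2"), c("from", "to"))
  for (pair in endpoint_names) {
    if (all(pair %in% names(raw))) {
      names(raw)[match(pair, names(raw))] <- c("from", "to")
      break
    }
  }
  if (!all(c("from", "to") %in% names(raw)) && ncol(raw) >= 2) {
    names(raw)[1:2] <- c("from", "to")
  }
  if (!("combined_score" %in% names(raw))) {
    stop_enorthern("edge list header must include combined_score",
                   "enorthern_parse_error")
  }
  interaction_graph(raw, nodes = nodes)
}

#' Restrict a graph to a gene set
#'
#' Takes the induced subgraph on the requested genes. Genes absent from the
#' graph are retained as isolated nodes and reported in the
#' `missing_genes` attribute, so a panel gene with no known interactions is
#' visible rather than silently dropped.
#'
#' @param graph An [interaction_graph()].
#' @param genes Non-empty character vector of gene symbols.
#' @return An [interaction_graph()] whose node set is exactly `genes`.
#' @export
purge_to_gene_set <- function(graph, genes) {
  stopifnot(inherits(graph, "interaction_graph"))
  genes <- unique(as.character(genes))
  if (length(genes) == 0) {
    stop_enorthern("gene set must be non-empty", "enorthern_validation_error")
  }
  known <- intersect(genes, graph_nodes(graph))
  sub <- igraph::induced_subgraph(graph$graph, known)
  edges <- tibble::as_tibble(igraph::as_data_frame(sub, what = "edges"))
  out <- interaction_graph(edges, nodes = genes)
  attr(out, "missing_genes") <- sort(setdiff(genes, graph_nodes(graph)))
  out
}

#' Nodes with no interactions
#'
#' @param graph An [interaction_graph()].
#' @return Sorted character vector of degree-zero node names.
#' @export
isolated_nodes <- function(graph) {
  stopifnot(inherits(graph, "interaction_graph"))
  deg <- igraph::degree(graph$graph)
  sort(names(deg)[deg == 0])
}

#' Rank genes by interaction degree
#'
#' Drops edges whose combined score falls below `min_score`, then ranks all
#' nodes by degree, descending, with alphabetical tie-breaking. Degree is
#' used because hub genes in functional-association networks are typically
#' read off as the most-connected nodes; no weighting or centrality beyond
#' raw degree is applied.
#'
#' @param graph An [interaction_graph()].
#' @param min_score Minimum combined score for an edge to count
#'   (default 0.4, STRING's historical medium-confidence cutoff).
#' @return Tibble with columns `gene` and `degree`, all nodes included.
#' @export
degree_ranking <- function(graph, min_score = 0.4) {
  stopifnot(inherits(graph, "interaction_graph"))
  g <- igraph::subgraph_from_edges(
    graph$graph,
    igraph::E(graph$graph)[igraph::E(graph$graph)$combined_score >= min_score],
    delete.vertices = FALSE
  )
  deg <- igraph::degree(g)
  out <- tibble::tibble(gene = names(deg), degree = as.integer(deg))
  out[order(-out$degree, out$gene), ]
}

#' Filter a graph to one evidence channel
#'
#' Keeps edges whose named evidence-channel score is at least `min_score`;
#' all nodes are preserved. Edges lacking a score for the channel are
#' dropped, since absence of evidence in a channel cannot support an
#' association through it.
#'
#' @param graph An [interaction_graph()].
#' @param channel One of the evidence channels present in the graph
#'   (e.g. `"coexpression"`).
#' @param min_score Minimum channel score in \[0, 1\].
#' @return An [interaction_graph()] on the same node set.
#' @export
channel_subgraph <- function(graph, channel, min_score) {
  stopifnot(inherits(graph, "interaction_graph"))
  if (!(channel %in% graph$channels)) {
    stop_enorthern(
      paste0("unknown evidence channel '", channel, "'; graph has: ",
             paste(graph$channels, collapse = ", ")),
      "enorthern_validation_error"
    )
  }
  edges <- graph_edges(graph)
  keep <- !is.na(edges[[channel]]) & edges[[channel]] >= min_score
  interaction_graph(edges[keep, , drop = FALSE], nodes = graph_nodes(graph))
}

#' Connected components of an interaction graph
#'
#' @param graph An [interaction_graph()].
#' @return List of character vectors (each sorted), one per component,
#'   ordered largest first with ties broken by first node name.
#' @export
connected_components <- function(graph) {
  stopifnot(inherits(graph, "interaction_graph"))
  comp <- igraph::components(graph$graph)
  groups <- split(names(comp$membership), comp$membership)
  groups <- lapply(groups, sort)
  ord <- order(-lengths(groups), vapply(groups, `[`, "", 1))
  unname(groups[ord])
}
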