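# Brute-force graph oracles, deliberately independent of igraph: plain
# adjacency counting and transitive closure over an edge data frame.

oracle_degrees <- function(edges, nodes) {
  deg <- setNames(rep(0L, length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    deg[[edges$from[i]]] <- deg[[edges$from[i]]] + 1L
    deg[[edges$to[i]]] <- deg[[edges$to[i]]] + 1L
  }
  deg
}

oracle_components <- function(edges, nodes) {
  comp <- lapply(nodes, identity)
  for (i in seq_len(nrow(edges))) {
    ia <- which(vapply(comp, function(s) edges$from[i] %in% s, logical(1)))
    ib <- which(vapply(comp, function(s) edges$to[i] %in% s, logical(1)))
    if (ia != ib) {
      comp[[ia]] <- union(comp[[ia]], comp[[ib]])
      comp <- comp[-ib]
    }
  }
  comp <- lapply(comp, sort)
  comp[order(-lengths(comp), vapply(comp, `[`, "", 1))]
}

random_edge_table <- function(n_nodes, p, scores = TRUE) {
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  pairs <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(pairs)) < p
  edges <- tibble::tibble(
    from = pairs[keep, 1], to = pairs[keep, 2],
    combined_score = if (scores) round(stats::runif(sum(keep)), 3) else rep(0.5, sum(keep))
  )
  list(nodes = nodes, edges = edges)
}

table2_fixture <- function() {
  read_study_table(enorthern_example("table2.tsv"))
}

# The independent relative-expression oracle: geometric mean via logarithms.
oracle_e_r <- function(ma, s, mu) {
  ifelse(s > 0 & mu > 0, exp(log(ma) - 0.5 * (log(s) + log(mu))), NA_real_)
}
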