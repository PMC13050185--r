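# Community detection and centrality summaries on the kinship network.

#' Louvain community detection on a kinship network
#'
#' Runs greedy modularity maximisation (Louvain) on the network, by default
#' using the total shared cM as edge weights where available. Isolated nodes
#' each form their own community.
#'
#' @param net a `kin_network`.
#' @param use_weights use IBD edge weights if present (modularity is
#'   invariant to rescaling the weights by a positive constant).
#' @param resolution Louvain resolution parameter.
#' @param seed integer seed fixing tie-breaking in the greedy moves.
#' @return List with `membership` (named integer vector, node id ->
#'   community), `modularity`, and `n_communities`.
#' @examples
#' fx <- make_avar_fixture(seed = 1)
#' louvain_communities(fx$network, seed = 1)$n_communities
#' @export
louvain_communities <- function(net, use_weights = TRUE, resolution = 1,
                                seed = 1) {
  stopifnot(inherits(net, "kin_network"), n_nodes(net) >= 1)
  g <- as_igraph(net)
  w <- NULL
  if (use_weights && "weight" %in% igraph::edge_attr_names(g)) {
    w <- igraph::E(g)$weight
    if (anyNA(w)) w <- NULL
  }
  cl <- .with_seed(seed,
                   igraph::cluster_louvain(g, weights = w,
                                           resolution = resolution))
  membership <- igraph::membership(cl)
  names(membership) <- igraph::V(g)$name
  list(membership = as.integer(membership) |>
         stats::setNames(names(membership)),
       modularity = igraph::modularity(cl),
       n_communities = length(unique(membership)))
}

#' Degree and betweenness centrality
#'
#' Degree is the incident edge count; betweenness is unnormalised
#' shortest-path betweenness on the unweighted graph (set `weighted = TRUE`
#' to use `1 / total shared cM` as edge distances, so that strongly
#' connected pairs are "closer").
#'
#' @param net a `kin_network`.
#' @param weighted use IBD-derived distances for betweenness.
#' @return Data frame with `id`, `degree`, `betweenness`.
#' @examples
#' nt <- node_table(data.frame(id = c("a", "b", "c"), x = c("1", "1", "2")))
#' net <- kin_network(nt, data.frame(i = c(1, 2), j = c(2, 3)))
#' centrality(net) # path graph: betweenness 0,1,0
#' @export
centrality <- function(net, weighted = FALSE) {
  stopifnot(inherits(net, "kin_network"))
  g <- as_igraph(net)
  w <- NA
  if (weighted && "weight" %in% igraph::edge_attr_names(g) &&
      !anyNA(igraph::E(g)$weight)) {
    w <- 1 / igraph::E(g)$weight
  }
  data.frame(
    id = igraph::V(g)$name,
    degree = as.integer(igraph::degree(g)),
    betweenness = igraph::betweenness(g, directed = FALSE, weights = w,
                                      normalized = FALSE),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
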