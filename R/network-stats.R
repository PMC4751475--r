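#' Graph primitives on induced subgraphs
#'
#' A cluster is a nonempty set of protein IDs interpreted as the subgraph
#' C = (Vc, Ec) induced on a bound network. \code{avedeg} is the average
#' degree 2|Ec|/|Vc|; \code{clusterDensity} is 2|Ec|/(|Vc|(|Vc|-1)), defined
#' as 0 for a single node; \code{neighborNodes} is N(C), the nodes outside
#' Vc adjacent to at least one member; \code{edgeCountTo} is edgeNum(v, C),
#' the number of edges connecting an outside node v to members of C.
#'
#' @param network an \linkS4class{InteractionNetwork}.
#' @param members nonempty character vector of protein IDs, all present in
#'   the network.
#' @param v a single protein ID not in \code{members}.
#' @return \code{avedeg}, \code{clusterDensity}: a real; \code{neighborNodes}:
#'   a character vector; \code{edgeCountTo}: an integer count.
#' @examples
#' net <- makeInteractionNetwork(c("a", "b", "c"), c("b", "c", "a"))
#' avedeg(net, c("a", "b", "c"))         # triangle: 2
#' clusterDensity(net, c("a", "b", "c")) # 1
#' @name graph-primitives
NULL

.checkMembers <- function(network, members) {
  members <- as.character(members)
  if (length(members) == 0) stop("cluster must be nonempty")
  miss <- setdiff(members, proteins(network))
  if (length(miss) > 0)
    stop("cluster member(s) not in network: ",
         paste(head(miss, 3), collapse = ", "))
  members
}

.inducedEdgeCount <- function(network, members) {
  igraph::ecount(igraph::induced_subgraph(networkGraph(network), members))
}

#' @rdname graph-primitives
#' @export
avedeg <- function(network, members) {
  members <- .checkMembers(network, members)
  2 * .inducedEdgeCount(network, members) / length(members)
}

#' @rdname graph-primitives
#' @export
clusterDensity <- function(network, members) {
  members <- .checkMembers(network, members)
  n <- length(members)
  if (n <= 1) return(0)
  2 * .inducedEdgeCount(network, members) / (n * (n - 1))
}

#' @rdname graph-primitives
#' @export
neighborNodes <- function(network, members) {
  members <- .checkMembers(network, members)
  g <- networkGraph(network)
  nb <- igraph::adjacent_vertices(g, members)
  ids <- unique(unlist(lapply(nb, function(vs) vs$name), use.names = FALSE))
  setdiff(ids, members)
}

#' @rdname graph-primitives
#' @export
edgeCountTo <- function(network, v, members) {
  members <- .checkMembers(network, members)
  v <- as.character(v)
  stopifnot(length(v) == 1)
  if (v %in% members) stop("v must lie outside the cluster")
  if (!v %in% proteins(network)) stop("node not in network: ", v)
  g <- networkGraph(network)
  nb <- igraph::neighbors(g, v)$name
  sum(nb %in% members)
}
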