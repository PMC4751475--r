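#' The 22-feature registry
#'
#' Names, in fixed order, of the 22 subgraph features: node size and graph
#' density, then six groups of statistics — degree (normalized by |Vc|-1),
#' degree correlation (per-node ratio of mean neighbor degree to own
#' degree), local clustering coefficient, topological coefficient, first
#' eigenvalues of the adjacency and Laplacian matrices, and protein
#' sequence-length / molecular-weight statistics. Models record this
#' registry; prediction refuses a model trained under a different one.
#'
#' @return character vector of length 22.
#' @export
featureRegistry <- function() {
  c("nodeSize", "graphDensity",
    "meanDegree", "maxDegree", "varDegree",
    "meanDegreeCorrelation", "maxDegreeCorrelation", "varDegreeCorrelation",
    "meanClusteringCoeff", "maxClusteringCoeff", "varClusteringCoeff",
    "meanTopologicalCoeff", "maxTopologicalCoeff", "varTopologicalCoeff",
    "firstEigenvalueAdjacency", "firstEigenvalueLaplacian",
    "meanLength", "maxLength", "varLength",
    "meanWeight", "maxWeight", "varWeight")
}

# population variance: a single observation has zero spread
.popVar <- function(x) {
  if (length(x) <= 1) return(0)
  mean((x - mean(x))^2)
}

.mmv <- function(x) c(mean(x), max(x), .popVar(x))

#' Compute the 22-feature vector of an induced subgraph
#'
#' All topology statistics are computed on the subgraph induced by
#' \code{members} only; the six length/weight features are 0 when no
#' attribute table is available (or covers none of the members).
#'
#' @param network an \linkS4class{InteractionNetwork}.
#' @param members nonempty character vector of member protein IDs.
#' @param attributes optional data.frame (rows named by protein ID, columns
#'   \code{length}, \code{weight}); defaults to the network's own table.
#' @return named numeric vector of length 22 (see
#'   \code{\link{featureRegistry}}).
#' @export
extractFeatures <- function(network, members,
                            attributes = nodeAttributes(network)) {
  members <- .checkMembers(network, members)
  g <- igraph::induced_subgraph(networkGraph(network), members)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  A[A > 0] <- 1 # feature space ignores edge weights / multiplicities
  lens <- wts <- rep(NA_real_, length(members))
  if (!is.null(attributes) && nrow(attributes) > 0) {
    ord <- rownames(A)
    hit <- match(ord, rownames(attributes))
    lens <- attributes$length[hit]
    wts <- attributes$weight[hit]
  }
  .featuresFromAdj(A, lens, wts)
}

# core feature computation on a 0/1 adjacency matrix; lens/wts may hold NA
.featuresFromAdj <- function(A, lens, wts) {
  n <- nrow(A)
  deg <- rowSums(A)

  dens <- if (n <= 1) 0 else sum(A) / (n * (n - 1))
  normDeg <- if (n <= 1) rep(0, n) else deg / (n - 1)

  # mean degree of within-subgraph neighbors over own degree; 0 if isolated
  degCor <- vapply(seq_len(n), function(i) {
    if (deg[i] == 0) return(0)
    mean(deg[A[i, ] > 0]) / deg[i]
  }, numeric(1))

  A2 <- A %*% A
  cc <- vapply(seq_len(n), function(i) {
    if (deg[i] < 2) return(0)
    tri <- sum(A2[i, ] * A[i, ]) / 2
    2 * tri / (deg[i] * (deg[i] - 1))
  }, numeric(1))

  # topological coefficient: mean shared-neighbor count over partner nodes,
  # scaled by own degree; 0 when degree < 2 or no partner shares a neighbor
  tc <- vapply(seq_len(n), function(i) {
    if (deg[i] < 2) return(0)
    shared <- A2[i, ]
    shared[i] <- 0
    partners <- shared > 0
    if (!any(partners)) return(0)
    mean(shared[partners]) / deg[i]
  }, numeric(1))

  eigA <- if (n == 0) 0 else max(eigen(A, symmetric = TRUE,
                                       only.values = TRUE)$values)
  L <- diag(deg, nrow = n) - A
  eigL <- if (n == 0) 0 else max(eigen(L, symmetric = TRUE,
                                       only.values = TRUE)$values)

  lenStats <- c(0, 0, 0); wtStats <- c(0, 0, 0)
  lens <- lens[!is.na(lens)]
  if (length(lens) > 0) lenStats <- .mmv(lens)
  wts <- wts[!is.na(wts)]
  if (length(wts) > 0) wtStats <- .mmv(wts)

  out <- c(n, dens, .mmv(normDeg), .mmv(degCor), .mmv(cc), .mmv(tc),
           eigA, eigL, lenStats, wtStats)
  names(out) <- featureRegistry()
  out
}

#' Feature matrix over a list of clusters
#'
#' @param network an \linkS4class{InteractionNetwork}.
#' @param sets list of member-set character vectors.
#' @param attributes optional attribute table (see
#'   \code{\link{extractFeatures}}).
#' @return numeric matrix, one row per set, 22 named columns.
#' @export
featureMatrix <- function(network, sets,
                          attributes = nodeAttributes(network)) {
  m <- t(vapply(sets, function(s) extractFeatures(network, s, attributes),
                numeric(length(featureRegistry()))))
  colnames(m) <- featureRegistry()
  m
}

#' Fit an equal-width binning scheme
#'
#' Per feature, the observed [min, max] over the training matrix is split
#' into \code{bins} equal-width intervals. A constant feature gets a
#' degenerate mapping (every value to bin 0).
#'
#' @param mat numeric matrix of feature vectors (rows = instances).
#' @param bins number of bins per feature (default 10).
#' @return a binning scheme: list with \code{lo}, \code{hi}, \code{width}
#'   (named numeric vectors) and \code{bins}.
#' @export
fitBinning <- function(mat, bins = 10L) {
  if (!is.matrix(mat) || nrow(mat) == 0) stop("need a nonempty matrix")
  bins <- as.integer(bins)
  if (bins < 2) stop("bins must be >= 2")
  lo <- apply(mat, 2, min)
  hi <- apply(mat, 2, max)
  list(lo = lo, hi = hi, width = (hi - lo) / bins, bins = bins)
}

#' Discretize feature vectors into item vectors
#'
#' Value v of a feature maps to bin floor((v - lo) / width), clipped into
#' [0, bins - 1]; values outside the training range clip to the boundary
#' bins, and the exact maximum falls into the last bin. Features that were
#' constant at fit time map everything to bin 0.
#'
#' @param x a named feature vector of length 22, or a feature matrix.
#' @param scheme a binning scheme from \code{\link{fitBinning}}.
#' @return integer vector (or matrix) of bin indices in [0, bins - 1].
#' @export
discretize <- function(x, scheme) {
  if (is.matrix(x)) {
    out <- t(apply(x, 1, discretize, scheme = scheme))
    colnames(out) <- colnames(x)
    return(out)
  }
  w <- scheme$width
  b <- ifelse(w > 0, floor((x - scheme$lo) / w), 0)
  b <- pmin(pmax(b, 0), scheme$bins - 1L)
  out <- as.integer(b)
  names(out) <- names(x)
  out
}
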