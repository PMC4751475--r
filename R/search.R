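#' Grow a candidate complex from a seed protein
#'
#' Implements the greedy growth loop: start from C = {seed}; at each step
#' take the single neighbor v of C with the most edges into C (ties broken
#' by lexicographic protein ID) and accept C' = C + v only if
#' f(C') >= f(C) and avedeg(C') > avedeg(C); the first rejection (or an
#' empty neighborhood) stops growth. The grown cluster is returned only
#' when f(C) > 1/2 and |C| >= minSize.
#'
#' @param network an \linkS4class{InteractionNetwork}.
#' @param model a \linkS4class{ContrastModel}.
#' @param seed a protein ID present in the network.
#' @param minSize minimum emitted size (default 3).
#' @param context optional precomputed network context (internal; built
#'   automatically, and shared across seeds by \code{detectComplexes}).
#' @return list with \code{members} (NULL when no complex was emitted),
#'   \code{f}, and \code{trace} (data.frame of the accepted growth path
#'   with columns step, added, f, avedeg).
#' @export
growFromSeed <- function(network, model, seed, minSize = 3L,
                         context = NULL) {
  seed <- as.character(seed)
  if (!seed %in% proteins(network)) stop("seed not in network: ", seed)
  ctx <- if (is.null(context)) .networkContext(network) else context
  scoreOf <- function(mem) {
    A <- as.matrix(ctx$adjMat[mem, mem, drop = FALSE])
    fv <- .featuresFromAdj(A, ctx$lens[mem], ctx$wts[mem])
    clusteringScore(discretize(fv, model@binning), model)
  }
  members <- seed
  nEdges <- 0
  f <- scoreOf(members)
  ad <- 0
  # frontier bookkeeping: edges from each neighbor of C into C
  cnt <- integer(0)
  nb <- ctx$adj[[seed]]
  if (length(nb) > 0) { cnt <- rep(1L, length(nb)); names(cnt) <- nb }
  steps <- list(list(step = 0L, added = seed, f = f, avedeg = ad))
  repeat {
    if (length(cnt) == 0) break
    best <- sort(names(cnt)[cnt == max(cnt)])[1]
    k <- cnt[[best]]
    n2 <- length(members) + 1L
    ad2 <- 2 * (nEdges + k) / n2
    if (!(ad2 > ad)) break # average degree must strictly increase
    cand <- c(members, best)
    f2 <- scoreOf(cand)
    if (!(f2 >= f)) break # clustering score must not decrease
    members <- cand; nEdges <- nEdges + k; f <- f2; ad <- ad2
    steps[[length(steps) + 1L]] <- list(step = length(steps), added = best,
                                        f = f, avedeg = ad)
    cnt <- cnt[names(cnt) != best]
    for (u in ctx$adj[[best]]) {
      if (u %in% members) next
      cnt[u] <- if (is.na(cnt[u])) 1L else cnt[[u]] + 1L
    }
  }
  trace <- do.call(rbind, lapply(steps, function(s)
    data.frame(step = s$step, added = s$added, f = s$f, avedeg = s$avedeg,
               stringsAsFactors = FALSE)))
  ok <- f > 0.5 && length(members) >= minSize
  list(members = if (ok) sort(members) else NULL, f = f, trace = trace)
}

# precomputed per-network structures shared across seeds
.networkContext <- function(network) {
  g <- networkGraph(network)
  nodes <- proteins(network)
  adjList <- igraph::as_adj_list(g)
  adj <- lapply(adjList, function(vs) nodes[as.integer(vs)])
  names(adj) <- nodes
  M <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  M@x[M@x > 0] <- 1
  attrs <- nodeAttributes(network)
  lens <- wts <- rep(NA_real_, length(nodes))
  names(lens) <- names(wts) <- nodes
  if (nrow(attrs) > 0) {
    hit <- match(nodes, rownames(attrs))
    lens[] <- attrs$length[hit]
    wts[] <- attrs$weight[hit]
  }
  list(adj = adj, adjMat = M, lens = lens, wts = wts)
}

#' Overlap score between two member sets
#'
#' omega(a, b) = |a intersect b|^2 / (|a| |b|), the neighborhood-affinity
#' overlap used both for merging predictions and for matching predictions
#' to reference complexes.
#'
#' @param a,b nonempty character vectors of protein IDs.
#' @return omega in [0, 1].
#' @export
overlapScore <- function(a, b) {
  if (length(a) == 0 || length(b) == 0)
    stop("overlap score is undefined for empty sets")
  length(intersect(a, b))^2 / (length(a) * length(b))
}

#' Merge highly overlapping complexes
#'
#' Repeatedly merges the pair with the highest overlap score omega >=
#' \code{threshold} into its union, recomputing overlaps after each merge,
#' until no pair qualifies. Ties are broken deterministically by the
#' lexicographic order of the sorted member sets.
#'
#' @param catalog a \linkS4class{ComplexCatalog}.
#' @param threshold merge threshold in (0, 1] (default 0.8).
#' @return the merged \linkS4class{ComplexCatalog} (scores dropped).
#' @export
mergeOverlapping <- function(catalog, threshold = 0.8) {
  stopifnot(threshold > 0, threshold <= 1)
  sets <- lapply(complexes(catalog), sort)
  repeat {
    n <- length(sets)
    if (n < 2) break
    bestI <- 0L; bestJ <- 0L; bestW <- -1
    keys <- vapply(sets, paste, character(1), collapse = "\r")
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      w <- overlapScore(sets[[i]], sets[[j]])
      if (w < threshold) next
      better <- w > bestW ||
        (w == bestW && (keys[i] < keys[bestI] ||
                        (keys[i] == keys[bestI] && keys[j] < keys[bestJ])))
      if (better) { bestW <- w; bestI <- i; bestJ <- j }
    }
    if (bestW < threshold) break
    merged <- sort(union(sets[[bestI]], sets[[bestJ]]))
    sets <- c(sets[-c(bestI, bestJ)], list(merged))
  }
  makeComplexCatalog(sets)
}

#' Detect protein complexes in a network with a trained model
#'
#' Seeds are taken in order of descending network degree (ties by
#' lexicographic ID) among proteins not yet covered by any emitted complex;
#' every processed seed is marked visited whether or not it yields a
#' complex, so the search always terminates. Duplicate member sets are
#' removed, highly overlapping complexes are merged, and the final
#' catalogue is filtered to f > 1/2 and size >= \code{minSize} so every
#' emitted complex satisfies the score criterion.
#'
#' @param network an \linkS4class{InteractionNetwork}.
#' @param model a \linkS4class{ContrastModel}.
#' @param minSize minimum complex size (default 3).
#' @param mergeThreshold overlap threshold for the merge step (default 0.8).
#' @param keepTrace record per-seed growth traces (default TRUE).
#' @return a \linkS4class{PredictionResult}.
#' @export
detectComplexes <- function(network, model, minSize = 3L,
                            mergeThreshold = 0.8, keepTrace = TRUE) {
  if (!identical(model@registry, featureRegistry()))
    stop("model feature registry does not match this build")
  g <- networkGraph(network)
  nodes <- proteins(network)
  deg <- igraph::degree(g)
  order <- nodes[order(-deg, nodes)]
  ctx <- .networkContext(network)
  covered <- character(0)
  visited <- character(0)
  found <- list(); fs <- numeric(0); traces <- list()
  for (seed in order) {
    if (seed %in% visited || seed %in% covered) next
    res <- growFromSeed(network, model, seed, minSize = minSize,
                        context = ctx)
    visited <- c(visited, seed)
    if (keepTrace) traces[[seed]] <- res$trace
    if (!is.null(res$members)) {
      found[[length(found) + 1L]] <- res$members
      fs <- c(fs, res$f)
      covered <- union(covered, res$members)
    }
  }
  if (length(found) > 0) {
    keys <- vapply(found, paste, character(1), collapse = "\r")
    keep <- !duplicated(keys)
    found <- found[keep]; fs <- fs[keep]
  }
  merged <- mergeOverlapping(makeComplexCatalog(found), mergeThreshold)
  sets <- complexes(merged)
  fFinal <- vapply(sets, function(s) scoreSubgraph(network, s, model),
                   numeric(1))
  keep <- fFinal > 0.5 & vapply(sets, length, integer(1)) >= minSize
  new("PredictionResult",
      catalog = makeComplexCatalog(sets[keep], fFinal[keep]),
      trace = traces)
}
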