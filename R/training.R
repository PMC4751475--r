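#' Map a complex catalogue onto a network as positive training instances
#'
#' Each catalogued complex is intersected with the network's protein set;
#' complexes left with fewer than 3 members are dropped (single proteins
#' and pairs carry no usable subgraph topology), and exact-duplicate member
#' sets are dropped keeping the first. Counts of dropped complexes are
#' reported via \code{message}.
#'
#' @param network an \linkS4class{InteractionNetwork}.
#' @param catalog a \linkS4class{ComplexCatalog} of true complexes.
#' @return list of member-set character vectors (sorted within each set).
#' @export
buildPositiveInstances <- function(network, catalog) {
  nodes <- proteins(network)
  sets <- lapply(complexes(catalog), function(s) sort(intersect(s, nodes)))
  small <- vapply(sets, length, integer(1)) < 3
  sets <- sets[!small]
  keys <- vapply(sets, paste, character(1), collapse = "\r")
  dup <- duplicated(keys)
  if (sum(small) + sum(dup) > 0)
    message("buildPositiveInstances: dropped ", sum(small),
            " complex(es) with <3 members in network and ", sum(dup),
            " duplicate(s)")
  sets[!dup]
}

#' Sample random subgraphs as negative training instances
#'
#' Draws \code{ratio} times as many random node sets as there are positive
#' instances. Each set's size is drawn uniformly from the empirical positive
#' size list, so the negatives reproduce the positives' size distribution by
#' construction; members are drawn uniformly without replacement from the
#' network's proteins. A draw identical to a positive member set is rejected
#' and redrawn.
#'
#' @param network an \linkS4class{InteractionNetwork}.
#' @param positiveSizes integer vector of positive-instance sizes.
#' @param ratio negatives per positive (default 20).
#' @param forbidden optional list of member sets a draw may not equal
#'   (typically the positive sets).
#' @return list of member-set character vectors, length
#'   \code{ratio * length(positiveSizes)}.
#' @export
sampleNegativeSubgraphs <- function(network, positiveSizes, ratio = 20L,
                                    forbidden = list()) {
  nodes <- proteins(network)
  positiveSizes <- as.integer(positiveSizes)
  if (length(positiveSizes) == 0) stop("no positive sizes supplied")
  if (max(positiveSizes) > length(nodes))
    stop("requested subgraph size exceeds network size")
  forbiddenKeys <- vapply(forbidden,
                          function(s) paste(sort(s), collapse = "\r"),
                          character(1))
  nDraw <- ratio * length(positiveSizes)
  sizes <- sample(positiveSizes, nDraw, replace = TRUE)
  out <- vector("list", nDraw)
  for (i in seq_len(nDraw)) {
    repeat {
      s <- sort(sample(nodes, sizes[i]))
      if (!(paste(s, collapse = "\r") %in% forbiddenKeys)) break
    }
    out[[i]] <- s
  }
  out
}

#' Assemble the positive and negative feature classes
#'
#' Composes \code{\link{buildPositiveInstances}},
#' \code{\link{sampleNegativeSubgraphs}} and feature extraction into a
#' \linkS4class{TrainingData} object. Deterministic for a fixed seed.
#'
#' @param network an \linkS4class{InteractionNetwork}.
#' @param catalog a \linkS4class{ComplexCatalog} of true complexes.
#' @param attributes optional attribute table; defaults to the network's.
#' @param ratio negatives per positive (default 20).
#' @param rngSeed integer seed for the negative sampling.
#' @return a \linkS4class{TrainingData}.
#' @export
assembleTrainingData <- function(network, catalog,
                                 attributes = nodeAttributes(network),
                                 ratio = 20L, rngSeed = 1L) {
  pos <- buildPositiveInstances(network, catalog)
  if (length(pos) < 2)
    stop("insufficient positives to learn contrasts (need >= 2, got ",
         length(pos), ")")
  set.seed(rngSeed)
  neg <- sampleNegativeSubgraphs(network,
                                 vapply(pos, length, integer(1)),
                                 ratio = ratio, forbidden = pos)
  new("TrainingData",
      positive = featureMatrix(network, pos, attributes),
      negative = featureMatrix(network, neg, attributes),
      positiveSets = pos, negativeSets = neg,
      rngSeed = as.integer(rngSeed))
}
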