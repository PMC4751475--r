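#' Aggregate, base, normalized and clustering scores
#'
#' \code{aggregateScore} sums the target-class supports of every NEP whose
#' itemset is contained in the instance's item vector. \code{baseScore} is
#' the median aggregate score of a class over its own training instances
#' (even counts average the two central values); when that median is zero
#' the smallest strictly positive per-instance score is used instead, and 1
#' if every score is zero, so normalization never divides by zero.
#' \code{normalizedScore} divides an aggregate score by a base score, and
#' \code{clusteringScoreValue} combines the two normalized scores as
#' f = np / (np + nn) (0 when both are zero), so that f > 1/2 exactly when
#' the positive normalized score exceeds the negative one, and f = 1
#' exactly when the instance matches no negative-class pattern while
#' matching at least one positive-class pattern.
#'
#' @param ins integer item vector (names = feature names).
#' @param eps list of NEPs (see \code{\link{mineNEPs}}).
#' @param classVectors integer matrix of the class's own item vectors.
#' @param base strictly positive base score.
#' @param np,nn normalized positive / negative scores (nonnegative).
#' @return a real score; \code{clusteringScoreValue} lies in [0, 1].
#' @name ep-scores
NULL

#' @rdname ep-scores
#' @export
aggregateScore <- function(ins, eps) {
  if (length(eps) == 0) return(0)
  total <- 0
  for (e in eps) {
    it <- e$items
    v <- ins[names(it)]
    if (!anyNA(v) && all(v == it)) total <- total + e$supportTarget
  }
  total
}

#' @rdname ep-scores
#' @export
baseScore <- function(eps, classVectors) {
  if (!is.matrix(classVectors) || nrow(classVectors) == 0)
    stop("class vectors must be a nonempty matrix")
  perInstance <- apply(classVectors, 1, aggregateScore, eps = eps)
  b <- median(perInstance)
  if (b == 0) {
    pos <- perInstance[perInstance > 0]
    b <- if (length(pos) > 0) min(pos) else 1
    warning("baseScore: class median is 0; falling back to ",
            format(b, digits = 4))
  }
  b
}

#' @rdname ep-scores
#' @export
normalizedScore <- function(ins, eps, base) {
  if (base <= 0) stop("base score must be strictly positive")
  aggregateScore(ins, eps) / base
}

#' @rdname ep-scores
#' @export
clusteringScoreValue <- function(np, nn) {
  if (np == 0 && nn == 0) return(0)
  np / (np + nn)
}

#' Clustering score of an item vector under a trained model
#'
#' @param ins integer item vector.
#' @param model a \linkS4class{ContrastModel}.
#' @return f in [0, 1]; f > 1/2 predicts "complex".
#' @export
clusteringScore <- function(ins, model) {
  np <- normalizedScore(ins, model@epPos, model@basePos)
  nn <- normalizedScore(ins, model@epNeg, model@baseNeg)
  clusteringScoreValue(np, nn)
}

#' Clustering score of a subgraph (extract, discretize, score)
#'
#' @param network an \linkS4class{InteractionNetwork}.
#' @param members member protein IDs of the subgraph.
#' @param model a \linkS4class{ContrastModel}.
#' @return f in [0, 1].
#' @export
scoreSubgraph <- function(network, members, model) {
  fv <- extractFeatures(network, members)
  clusteringScore(discretize(fv, model@binning), model)
}

#' Train a contrast model from a network and a true-complex catalogue
#'
#' Runs the full training pipeline: positive instances mapped from the
#' catalogue, random negative subgraphs at \code{negRatio} per positive,
#' feature extraction, equal-width binning fitted on the pooled classes,
#' NEP mining in both directions, and base-score computation. Deterministic
#' for a fixed \code{rngSeed}.
#'
#' @param network an \linkS4class{InteractionNetwork}.
#' @param catalog a \linkS4class{ComplexCatalog} of true complexes.
#' @param attributes optional attribute table; defaults to the network's.
#' @param negRatio negatives per positive (default 20).
#' @param bins equal-width bins per feature (default 10).
#' @param delta1 background-rarity threshold (default 0.1).
#' @param delta2 target-frequency threshold (default 0.7).
#' @param rngSeed integer seed (default 1).
#' @return a \linkS4class{ContrastModel}.
#' @export
trainModel <- function(network, catalog,
                       attributes = nodeAttributes(network),
                       negRatio = 20L, bins = 10L,
                       delta1 = 0.1, delta2 = 0.7, rngSeed = 1L) {
  .checkDeltas(delta1, delta2)
  td <- assembleTrainingData(network, catalog, attributes,
                             ratio = negRatio, rngSeed = rngSeed)
  scheme <- fitBinning(rbind(td@positive, td@negative), bins = bins)
  dp <- discretize(td@positive, scheme)
  dn <- discretize(td@negative, scheme)
  eps <- mineBothClasses(dp, dn, delta1, delta2)
  if (length(eps$epPos) == 0)
    warning("no NEPs found for the positive class")
  if (length(eps$epNeg) == 0)
    warning("no NEPs found for the negative class")
  new("ContrastModel",
      epPos = eps$epPos, epNeg = eps$epNeg, binning = scheme,
      basePos = baseScore(eps$epPos, dp),
      baseNeg = baseScore(eps$epNeg, dn),
      delta1 = delta1, delta2 = delta2,
      params = list(negRatio = as.integer(negRatio),
                    bins = as.integer(bins),
                    rngSeed = as.integer(rngSeed),
                    nPositive = nrow(dp), nNegative = nrow(dn)),
      registry = featureRegistry())
}

.nepToJSON <- function(e) {
  list(items = mapply(function(f, b) list(f, b), names(e$items),
                      unname(e$items), SIMPLIFY = FALSE, USE.NAMES = FALSE),
       support_target = e$supportTarget,
       support_background = e$supportBackground)
}

.nepFromJSON <- function(x) {
  items <- vapply(x$items, function(p) as.integer(p[[2]]), integer(1))
  names(items) <- vapply(x$items, function(p) as.character(p[[1]]),
                         character(1))
  list(items = items, supportTarget = as.numeric(x$support_target),
       supportBackground = as.numeric(x$support_background))
}

#' Serialize / deserialize a trained model as JSON
#'
#' The file records a schema version, the feature registry, the binning
#' scheme, both NEP sets with their supports, the base scores and the
#' training parameters, so a model trained on one network can be applied to
#' any other network sharing the registry.
#'
#' @param model a \linkS4class{ContrastModel}.
#' @param path destination / source file.
#' @return \code{writeModel}: the path, invisibly; \code{readModel}: a
#'   \linkS4class{ContrastModel}.
#' @export
writeModel <- function(model, path) {
  obj <- list(
    schema_version = 1L,
    registry = featureRegistry(),
    binning = list(lo = unname(model@binning$lo),
                   hi = unname(model@binning$hi),
                   bins = model@binning$bins),
    ep_pos = lapply(model@epPos, .nepToJSON),
    ep_neg = lapply(model@epNeg, .nepToJSON),
    base_pos = model@basePos, base_neg = model@baseNeg,
    delta1 = model@delta1, delta2 = model@delta2,
    params = model@params)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- jsonlite::read_json(path)
  if (is.null(obj$schema_version) || is.null(obj$registry))
    stop("not a valid model file (missing schema fields): ", path)
  reg <- unlist(obj$registry)
  if (!identical(reg, featureRegistry()))
    stop("feature registry in model file does not match this build")
  lo <- as.numeric(unlist(obj$binning$lo))
  hi <- as.numeric(unlist(obj$binning$hi))
  names(lo) <- names(hi) <- reg
  bins <- as.integer(obj$binning$bins)
  new("ContrastModel",
      epPos = lapply(obj$ep_pos, .nepFromJSON),
      epNeg = lapply(obj$ep_neg, .nepFromJSON),
      binning = list(lo = lo, hi = hi, width = (hi - lo) / bins,
                     bins = bins),
      basePos = as.numeric(obj$base_pos),
      baseNeg = as.numeric(obj$base_neg),
      delta1 = as.numeric(obj$delta1), delta2 = as.numeric(obj$delta2),
      params = lapply(obj$params, function(p)
        if (is.numeric(p) && p == round(p)) as.integer(p) else p),
      registry = reg)
}
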