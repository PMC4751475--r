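#' @import methods
#' @importFrom stats median var rlnorm runif
#' @importFrom utils head combn
NULL

setOldClass("igraph")

#' InteractionNetwork: an undirected PPI network
#'
#' Wraps an undirected simple \pkg{igraph} graph whose vertices are protein
#' IDs, together with an optional per-protein attribute table (sequence
#' length in residues, molecular weight). Self-loops and duplicate edges are
#' never present; edge weights, when read from a file, are stored on the
#' graph but not used by the detection algorithm.
#'
#' @slot graph an undirected simple \code{igraph} with named vertices.
#' @slot attributes data.frame with columns \code{length} and \code{weight},
#'   row names are protein IDs; zero rows when no attribute table was given.
#'
#' @aliases InteractionNetwork
#' @exportClass InteractionNetwork
setClass("InteractionNetwork",
  representation(graph = "igraph", attributes = "data.frame"),
  prototype(attributes = data.frame(length = numeric(0), weight = numeric(0)))
)

setValidity("InteractionNetwork", function(object) {
  g <- object@graph
  msg <- character(0)
  if (igraph::is_directed(g))
    msg <- c(msg, "graph must be undirected")
  if (igraph::vcount(g) > 0 && is.null(igraph::V(g)$name))
    msg <- c(msg, "vertices must be named protein IDs")
  if (igraph::any_loop(g))
    msg <- c(msg, "self-loops are not allowed")
  if (igraph::any_multiple(g))
    msg <- c(msg, "duplicate edges are not allowed")
  a <- object@attributes
  if (nrow(a) > 0) {
    if (!all(c("length", "weight") %in% colnames(a)))
      msg <- c(msg, "attributes need 'length' and 'weight' columns")
    else if (any(!is.na(a$length) & a$length <= 0))
      msg <- c(msg, "sequence lengths must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' ComplexCatalog: an ordered list of protein complexes
#'
#' Each complex is a character vector of protein IDs (a member set). The
#' catalogue may carry optional names and per-complex scores.
#'
#' @slot complexes list of character vectors, each nonempty and duplicate-free.
#' @slot scores numeric, per-complex score (length 0 or one per complex).
#'
#' @aliases ComplexCatalog
#' @exportClass ComplexCatalog
setClass("ComplexCatalog",
  representation(complexes = "list", scores = "numeric"),
  prototype(complexes = list(), scores = numeric(0))
)

setValidity("ComplexCatalog", function(object) {
  msg <- character(0)
  if (!all(vapply(object@complexes, is.character, logical(1))))
    msg <- c(msg, "complexes must be character vectors of protein IDs")
  if (any(vapply(object@complexes, length, integer(1)) == 0))
    msg <- c(msg, "no complex may be empty")
  if (any(vapply(object@complexes, anyDuplicated, integer(1)) > 0))
    msg <- c(msg, "member IDs must be unique within a complex")
  ns <- length(object@scores)
  if (ns != 0 && ns != length(object@complexes))
    msg <- c(msg, "scores must be empty or one per complex")
  if (length(msg)) msg else TRUE
})

#' TrainingData: feature matrices for the positive and negative classes
#'
#' @slot positive numeric matrix, one row per true-complex instance, 22
#'   feature columns (the positive class Dp).
#' @slot negative numeric matrix of random-subgraph instances (Dn).
#' @slot positiveSets,negativeSets provenance: the member sets each row was
#'   computed from.
#' @slot rngSeed integer seed the negatives were drawn under.
#'
#' @aliases TrainingData
#' @exportClass TrainingData
setClass("TrainingData",
  representation(positive = "matrix", negative = "matrix",
                 positiveSets = "list", negativeSets = "list",
                 rngSeed = "integer")
)

setValidity("TrainingData", function(object) {
  msg <- character(0)
  if (ncol(object@positive) != length(featureRegistry()) ||
      ncol(object@negative) != length(featureRegistry()))
    msg <- c(msg, "feature matrices must have one column per registry feature")
  if (nrow(object@positive) != length(object@positiveSets))
    msg <- c(msg, "positive provenance does not match matrix rows")
  if (nrow(object@negative) != length(object@negativeSets))
    msg <- c(msg, "negative provenance does not match matrix rows")
  if (length(msg)) msg else TRUE
})

#' ContrastModel: a trained NEP-based complex detector
#'
#' Bundles everything prediction needs: the NEPs of the positive class
#' EP(Dp) and of the negative class EP(Dn), the equal-width binning scheme
#' fitted on the training data D = Dp U Dn, the two base scores used for
#' normalization, the mining thresholds, and the feature registry version.
#'
#' @slot epPos,epNeg lists of NEPs; each NEP is a list with elements
#'   \code{items} (named integer vector: bin index keyed by feature name),
#'   \code{supportTarget} and \code{supportBackground}.
#' @slot binning binning scheme as returned by \code{\link{fitBinning}}.
#' @slot basePos,baseNeg strictly positive base scores (class medians with
#'   the zero-guard fallback applied).
#' @slot delta1,delta2 the NEP support thresholds used at training time.
#' @slot params list of remaining training parameters (negRatio, minSize,
#'   mergeThreshold, rngSeed, counts).
#' @slot registry character vector of the 22 feature names, in order.
#'
#' @aliases ContrastModel
#' @exportClass ContrastModel
setClass("ContrastModel",
  representation(epPos = "list", epNeg = "list", binning = "list",
                 basePos = "numeric", baseNeg = "numeric",
                 delta1 = "numeric", delta2 = "numeric",
                 params = "list", registry = "character")
)

setValidity("ContrastModel", function(object) {
  msg <- character(0)
  if (object@basePos <= 0 || object@baseNeg <= 0)
    msg <- c(msg, "base scores must be strictly positive")
  if (!(object@delta1 > 0 && object@delta1 < object@delta2 &&
        object@delta2 <= 1))
    msg <- c(msg, "need 0 < delta1 < delta2 <= 1")
  if (!identical(object@registry, featureRegistry()))
    msg <- c(msg, "feature registry mismatch with this build")
  if (length(msg)) msg else TRUE
})

#' PredictionResult: detected complexes plus their growth trace
#'
#' @slot catalog ComplexCatalog of emitted complexes; \code{scores(catalog)}
#'   holds the clustering score f of each.
#' @slot trace list of per-seed growth logs (seed, accepted member sequence,
#'   f and average-degree values along the path).
#'
#' @aliases PredictionResult
#' @exportClass PredictionResult
setClass("PredictionResult",
  representation(catalog = "ComplexCatalog", trace = "list")
)

#' EvaluationReport: the full measure suite for predicted complexes
#'
#' @slot precision,recall,f1 match-based measures at the overlap threshold.
#' @slot sen,ppv,acc clustering-wise sensitivity, positive predictive value
#'   and their geometric mean.
#' @slot mmr maximum matching ratio.
#' @slot composite recall (Frac) + acc + mmr.
#' @slot counts named integer vector: nS, nP, nSt, nSp.
#' @slot threshold the overlap-score matching threshold used.
#'
#' @aliases EvaluationReport
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  representation(precision = "numeric", recall = "numeric", f1 = "numeric",
                 sen = "numeric", ppv = "numeric", acc = "numeric",
                 mmr = "numeric", composite = "numeric",
                 counts = "integer", threshold = "numeric")
)

setValidity("EvaluationReport", function(object) {
  vals <- c(object@precision, object@recall, object@f1, object@sen,
            object@ppv, object@acc, object@mmr)
  msg <- character(0)
  if (any(vals < -1e-12 | vals > 1 + 1e-12))
    msg <- c(msg, "all unit measures must lie in [0, 1]")
  if (abs(object@acc^2 - object@sen * object@ppv) > 1e-9)
    msg <- c(msg, "acc must be the geometric mean of sen and ppv")
  if (length(msg)) msg else TRUE
})
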