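#' Accessors for ContrastComplex classes
#'
#' @param x,object an object of the documented classes.
#' @param value replacement value.
#' @name accessors
NULL

#' @describeIn accessors protein IDs of a network.
#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))

#' @describeIn accessors number of interactions (edges) in a network.
#' @export
setGeneric("interactionCount", function(x) standardGeneric("interactionCount"))

#' @describeIn accessors the backing igraph of a network.
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' @describeIn accessors per-protein attribute table (length, weight).
#' @export
setGeneric("nodeAttributes", function(x) standardGeneric("nodeAttributes"))

#' @describeIn accessors attach a per-protein attribute table.
#' @export
setGeneric("nodeAttributes<-",
           function(x, value) standardGeneric("nodeAttributes<-"))

#' @describeIn accessors list of member sets of a catalogue.
#' @export
setGeneric("complexes", function(x) standardGeneric("complexes"))

#' @describeIn accessors per-complex scores of a catalogue or prediction.
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @describeIn accessors the catalogue inside a PredictionResult.
#' @export
setGeneric("predictedCatalog", function(x) standardGeneric("predictedCatalog"))

#' @describeIn accessors per-seed growth trace of a PredictionResult.
#' @export
setGeneric("growthTrace", function(x) standardGeneric("growthTrace"))

setMethod("proteins", "InteractionNetwork", function(x) {
  if (igraph::vcount(x@graph) == 0) character(0)
  else as.character(igraph::V(x@graph)$name)
})

setMethod("interactionCount", "InteractionNetwork",
          function(x) igraph::ecount(x@graph))

setMethod("networkGraph", "InteractionNetwork", function(x) x@graph)

setMethod("nodeAttributes", "InteractionNetwork", function(x) x@attributes)

setMethod("nodeAttributes<-", "InteractionNetwork", function(x, value) {
  x@attributes <- value
  validObject(x)
  x
})

setMethod("complexes", "ComplexCatalog", function(x) x@complexes)

setMethod("scores", "ComplexCatalog", function(x) x@scores)

#' @describeIn accessors number of complexes in a catalogue.
#' @export
setMethod("length", "ComplexCatalog", function(x) length(x@complexes))

setMethod("complexes", "PredictionResult", function(x) x@catalog@complexes)
setMethod("scores", "PredictionResult", function(x) x@catalog@scores)
setMethod("predictedCatalog", "PredictionResult", function(x) x@catalog)
setMethod("growthTrace", "PredictionResult", function(x) x@trace)

setMethod("show", "InteractionNetwork", function(object) {
  cat("InteractionNetwork with", igraph::vcount(object@graph), "proteins and",
      igraph::ecount(object@graph), "interactions\n")
  if (nrow(object@attributes) > 0)
    cat("  attributes (length, weight) for", nrow(object@attributes),
        "proteins\n")
})

setMethod("show", "ComplexCatalog", function(object) {
  n <- length(object@complexes)
  sz <- vapply(object@complexes, length, integer(1))
  cat("ComplexCatalog with", n, "complexes")
  if (n > 0) cat("; sizes", min(sz), "-", max(sz))
  cat("\n")
})

setMethod("show", "TrainingData", function(object) {
  cat("TrainingData: |Dp| =", nrow(object@positive),
      ", |Dn| =", nrow(object@negative),
      ", seed =", object@rngSeed, "\n")
})

setMethod("show", "ContrastModel", function(object) {
  cat("ContrastModel\n")
  cat("  EP(Dp):", length(object@epPos), "NEPs   EP(Dn):",
      length(object@epNeg), "NEPs\n")
  cat("  base scores:", format(object@basePos, digits = 4), "(pos)",
      format(object@baseNeg, digits = 4), "(neg)\n")
  cat("  thresholds: delta1 =", object@delta1, ", delta2 =", object@delta2,
      ", bins =", object@binning$bins, "\n")
})

setMethod("show", "PredictionResult", function(object) {
  cat("PredictionResult with", length(object@catalog@complexes),
      "predicted complexes\n")
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport (omega >=", object@threshold, ")\n")
  cat(sprintf("  precision %.3f  recall/Frac %.3f  F1 %.3f\n",
              object@precision, object@recall, object@f1))
  cat(sprintf("  Sen %.3f  PPV %.3f  Acc %.3f  MMR %.3f\n",
              object@sen, object@ppv, object@acc, object@mmr))
  cat(sprintf("  composite %.3f   (|S|=%d |P|=%d |St|=%d |Sp|=%d)\n",
              object@composite, object@counts[["nS"]], object@counts[["nP"]],
              object@counts[["nSt"]], object@counts[["nSp"]]))
})
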