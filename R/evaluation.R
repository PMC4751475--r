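#' Match reference and predicted complexes at an overlap threshold
#'
#' St is the set of reference complexes matched by at least one prediction
#' with omega >= threshold; Sp is the set of predictions matched by at
#' least one reference.
#'
#' @param S reference \linkS4class{ComplexCatalog}.
#' @param P predicted \linkS4class{ComplexCatalog}.
#' @param threshold overlap-score matching threshold (default 0.25,
#'   inclusive).
#' @return list with logical vectors \code{st} (over S) and \code{sp}
#'   (over P), and the omega matrix \code{omega} (|S| x |P|).
#' @export
matchSets <- function(S, P, threshold = 0.25) {
  s <- complexes(S); p <- complexes(P)
  if (length(s) == 0 || length(p) == 0) {
    warning("empty catalogue supplied; no matches possible")
    return(list(st = logical(length(s)), sp = logical(length(p)),
                omega = matrix(0, length(s), length(p))))
  }
  om <- outer(seq_along(s), seq_along(p),
              Vectorize(function(i, j) overlapScore(s[[i]], p[[j]])))
  list(st = apply(om, 1, max) >= threshold,
       sp = apply(om, 2, max) >= threshold,
       omega = om)
}

#' Precision, recall (Frac) and F1 of a predicted complex set
#'
#' precision = |Sp|/|P|, recall = |St|/|S| (the fraction of reference
#' complexes matched, "Frac"), and F1 their harmonic mean (0 when both are
#' 0).
#'
#' @inheritParams matchSets
#' @return named numeric vector (precision, recall, f1).
#' @export
precisionRecallF1 <- function(S, P, threshold = 0.25) {
  m <- matchSets(S, P, threshold)
  precision <- if (length(m$sp) == 0) 0 else mean(m$sp)
  recall <- if (length(m$st) == 0) 0 else mean(m$st)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

.intersectionMatrix <- function(S, P) {
  s <- complexes(S); p <- complexes(P)
  outer(seq_along(s), seq_along(p),
        Vectorize(function(i, j) length(intersect(s[[i]], p[[j]]))))
}

#' Clustering-wise sensitivity, PPV and geometric accuracy
#'
#' From the intersection matrix T (T_ij = shared proteins of reference i
#' and prediction j): Sen = sum_i max_j T_ij / sum_i |s_i|;
#' PPV = sum_j max_i T_ij / sum_ij T_ij (predictions sharing no protein
#' with any reference contribute zero to both sums); Acc = sqrt(Sen * PPV).
#'
#' @inheritParams matchSets
#' @return named numeric vector (sen, ppv, acc).
#' @export
geometricAccuracy <- function(S, P) {
  s <- complexes(S); p <- complexes(P)
  if (length(s) == 0 || length(p) == 0)
    return(c(sen = 0, ppv = 0, acc = 0))
  T <- .intersectionMatrix(S, P)
  sen <- sum(apply(T, 1, max)) / sum(vapply(s, length, integer(1)))
  tot <- sum(T)
  if (tot == 0) {
    warning("no protein shared between references and predictions")
    return(c(sen = sen, ppv = 0, acc = 0))
  }
  ppv <- sum(apply(T, 2, max)) / tot
  c(sen = sen, ppv = ppv, acc = sqrt(sen * ppv))
}

#' Maximum matching ratio (MMR)
#'
#' Builds the bipartite graph connecting each reference s to each
#' prediction p with weight omega(s, p) whenever omega > 0, finds an exact
#' maximum-weight matching (each complex incident to at most one selected
#' edge), and returns the total selected weight divided by |S|.
#'
#' @inheritParams matchSets
#' @return MMR in [0, 1].
#' @export
maximumMatchingRatio <- function(S, P) {
  s <- complexes(S); p <- complexes(P)
  if (length(s) == 0) return(0)
  if (length(p) == 0) return(0)
  om <- outer(seq_along(s), seq_along(p),
              Vectorize(function(i, j) overlapScore(s[[i]], p[[j]])))
  idx <- which(om > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0)
  g <- igraph::make_empty_graph(n = length(s) + length(p), directed = FALSE)
  igraph::V(g)$type <- c(rep(FALSE, length(s)), rep(TRUE, length(p)))
  g <- igraph::add_edges(g, rbind(idx[, 1], length(s) + idx[, 2]))
  m <- igraph::max_bipartite_match(g, weights = om[idx])
  m$matching_weight / length(s)
}

#' Evaluate a predicted complex set against a reference catalogue
#'
#' Computes the complete measure suite in one pass: precision / recall
#' (Frac) / F1 at the omega threshold, clustering-wise Sen / PPV and their
#' geometric mean Acc, the maximum matching ratio, and the composite score
#' Frac + Acc + MMR.
#'
#' @inheritParams matchSets
#' @return an \linkS4class{EvaluationReport}.
#' @export
evaluateComplexes <- function(S, P, threshold = 0.25) {
  m <- suppressWarnings(matchSets(S, P, threshold))
  precision <- if (length(m$sp) == 0) 0 else mean(m$sp)
  recall <- if (length(m$st) == 0) 0 else mean(m$st)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  ga <- suppressWarnings(geometricAccuracy(S, P))
  mmr <- maximumMatchingRatio(S, P)
  new("EvaluationReport",
      precision = precision, recall = recall, f1 = f1,
      sen = unname(ga["sen"]), ppv = unname(ga["ppv"]),
      acc = unname(ga["acc"]), mmr = mmr,
      composite = recall + unname(ga["acc"]) + mmr,
      counts = c(nS = length(S), nP = length(P),
                 nSt = sum(m$st), nSp = sum(m$sp)),
      threshold = threshold)
}

#' Write an evaluation report as JSON and/or one-line TSV
#'
#' @param report an \linkS4class{EvaluationReport}.
#' @param path destination file; extension \code{.tsv} selects the TSV
#'   form, anything else JSON.
#' @return the path, invisibly.
#' @export
writeReport <- function(report, path) {
  vals <- list(precision = report@precision, recall = report@recall,
               f1 = report@f1, sen = report@sen, ppv = report@ppv,
               acc = report@acc, mmr = report@mmr,
               composite = report@composite,
               threshold = report@threshold,
               counts = as.list(report@counts))
  if (grepl("\\.tsv$", path)) {
    hdr <- c("precision", "recall", "f1", "sen", "ppv", "acc", "mmr",
             "composite", "threshold", "nS", "nP", "nSt", "nSp")
    row <- c(report@precision, report@recall, report@f1, report@sen,
             report@ppv, report@acc, report@mmr, report@composite,
             report@threshold, report@counts)
    writeLines(c(paste(hdr, collapse = "\t"),
                 paste(format(row, trim = TRUE), collapse = "\t")), path)
  } else {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
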