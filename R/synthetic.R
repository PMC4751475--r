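#' Generate a synthetic planted-complex benchmark
#'
#' Builds a sparse Erdos-Renyi background network, plants \code{nComplexes}
#' node-disjoint complexes whose sizes follow a truncated power law
#' (P(s) proportional to s^-sizeExponent on [sizeMin, sizeMax]), wires each
#' planted complex internally with independent edge probability
#' \code{plantedDensity} plus a random spanning path so it is connected,
#' and attaches every complex to the background with
#' \code{attachmentEdges} random outward edges so planted complexes are not
#' trivially separated components. Protein attributes are sampled from a
#' log-normal sequence-length law with molecular weight a linear map of
#' length. Deterministic for a fixed seed.
#'
#' @param nBackgroundNodes number of proteins (default 300).
#' @param backgroundEdgeProb background edge probability (default 0.02).
#' @param nComplexes number of planted complexes (default 20).
#' @param sizeMin,sizeMax complex size range (defaults 3 and 10).
#' @param sizeExponent power-law exponent of the size law (default 2).
#' @param plantedDensity internal edge probability of planted complexes
#'   (default 0.8); must be at least \code{backgroundEdgeProb}.
#' @param attachmentEdges outward edges per planted complex (default 2).
#' @param lengthMeanlog,lengthSdlog log-normal parameters of sequence
#'   length in residues (defaults 6 and 0.45, median ~400 residues).
#' @param weightPerResidue molecular weight per residue in kDa
#'   (default 0.11).
#' @param rngSeed integer seed (default 1).
#' @return list with elements \code{network} (attributes attached),
#'   \code{catalog} (the planted complexes) and \code{attributes}.
#' @export
generateBenchmark <- function(nBackgroundNodes = 300L,
                              backgroundEdgeProb = 0.02,
                              nComplexes = 20L,
                              sizeMin = 3L, sizeMax = 10L,
                              sizeExponent = 2,
                              plantedDensity = 0.8,
                              attachmentEdges = 2L,
                              lengthMeanlog = 6, lengthSdlog = 0.45,
                              weightPerResidue = 0.11,
                              rngSeed = 1L) {
  stopifnot(sizeMin >= 3, sizeMax >= sizeMin,
            plantedDensity > 0, plantedDensity <= 1,
            backgroundEdgeProb >= 0, backgroundEdgeProb <= 1)
  if (plantedDensity < backgroundEdgeProb)
    stop("planted complexes must be at least as dense as the background")
  set.seed(rngSeed)

  ids <- sprintf("P%04d", seq_len(nBackgroundNodes))
  sizes <- sizeMin:sizeMax
  sz <- sample(sizes, nComplexes, replace = TRUE,
               prob = sizes^(-sizeExponent))
  if (sum(sz) > nBackgroundNodes)
    stop("planted complex sizes exceed the node budget")

  # background graph
  g <- igraph::sample_gnp(nBackgroundNodes, backgroundEdgeProb,
                          directed = FALSE)
  el <- igraph::as_edgelist(g)
  from <- ids[el[, 1]]; to <- ids[el[, 2]]

  # node-disjoint planted member sets
  pool <- sample(ids)
  sets <- vector("list", nComplexes)
  off <- 0L
  for (k in seq_len(nComplexes)) {
    sets[[k]] <- sort(pool[(off + 1):(off + sz[k])])
    off <- off + sz[k]
  }

  for (k in seq_len(nComplexes)) {
    mem <- sets[[k]]; m <- length(mem)
    pairs <- t(combn(mem, 2))
    keep <- runif(nrow(pairs)) < plantedDensity
    # random spanning path guarantees connectivity
    perm <- sample(mem)
    from <- c(from, pairs[keep, 1], perm[-m])
    to <- c(to, pairs[keep, 2], perm[-1])
    if (attachmentEdges > 0) {
      outside <- setdiff(ids, mem)
      from <- c(from, sample(mem, attachmentEdges, replace = TRUE))
      to <- c(to, sample(outside, attachmentEdges, replace = TRUE))
    }
  }

  lens <- pmax(50, round(rlnorm(nBackgroundNodes, lengthMeanlog,
                                lengthSdlog)))
  attrs <- data.frame(length = lens,
                      weight = round(lens * weightPerResidue, 2),
                      row.names = ids)

  net <- makeInteractionNetwork(from, to, nodes = ids)
  nodeAttributes(net) <- attrs
  list(network = net, catalog = makeComplexCatalog(sets),
       attributes = attrs)
}

#' Split a complex catalogue into train and test halves
#'
#' @param catalog a \linkS4class{ComplexCatalog}.
#' @param trainFraction fraction assigned to the training half, in (0, 1).
#' @param rngSeed integer seed.
#' @return list with \linkS4class{ComplexCatalog} elements \code{train} and
#'   \code{test} (disjoint partition of the catalogue entries).
#' @export
splitCatalog <- function(catalog, trainFraction = 0.5, rngSeed = 1L) {
  stopifnot(trainFraction > 0, trainFraction < 1)
  n <- length(catalog)
  nTrain <- round(n * trainFraction)
  if (nTrain == 0 || nTrain == n)
    stop("degenerate split: one side would be empty")
  set.seed(rngSeed)
  idx <- sample(n, nTrain)
  list(train = makeComplexCatalog(complexes(catalog)[idx]),
       test = makeComplexCatalog(complexes(catalog)[-idx]))
}
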