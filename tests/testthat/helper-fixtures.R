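# in-code fixtures shared across the suite

# small named graphs
netFromEdges <- function(from, to, ...) makeInteractionNetwork(from, to, ...)

triangleNet <- function() netFromEdges(c("a", "b", "c"), c("b", "c", "a"))

pathNet <- function() netFromEdges(c("a", "b"), c("b", "c"))

cliqueNet <- function(ids) {
  pr <- t(combn(ids, 2))
  netFromEdges(pr[, 1], pr[, 2])
}

# network of k node-disjoint cliques of size s plus optional spokes
multiCliqueNet <- function(k, s, spokes = TRUE) {
  ids <- sprintf("N%03d", seq_len(k * s + k))
  from <- character(0); to <- character(0)
  sets <- list()
  for (i in seq_len(k)) {
    mem <- ids[((i - 1) * s + 1):(i * s)]
    sets[[i]] <- mem
    pr <- t(combn(mem, 2))
    from <- c(from, pr[, 1]); to <- c(to, pr[, 2])
    if (spokes) { # one pendant node per clique so N(C) is nonempty
      from <- c(from, mem[1]); to <- c(to, ids[k * s + i])
    }
  }
  list(network = netFromEdges(from, to), sets = sets)
}

# random discretized two-class instance for miner/oracle comparisons
randomItemInstance <- function(seed, maxFeat = 6L, maxBins = 4L,
                               maxRows = 40L) {
  set.seed(seed)
  nf <- sample(2:maxFeat, 1)
  nb <- sample(2:maxBins, 1)
  nB <- sample(5:maxRows, 1)
  nT <- sample(5:maxRows, 1)
  bg <- matrix(sample(0:(nb - 1), nB * nf, replace = TRUE), nB, nf)
  # bias the target so frequent items exist
  tg <- matrix(sample(0:(nb - 1), nT * nf, replace = TRUE,
                      prob = seq(nb, 1)), nT, nf)
  colnames(bg) <- colnames(tg) <- paste0("F", seq_len(nf))
  list(background = bg, target = tg,
       delta1 = runif(1, 0, 0.2), delta2 = runif(1, 0.5, 1))
}

# exhaustive maximum-weight bipartite matching by recursion over rows
bruteForceMatchingWeight <- function(w) {
  n <- nrow(w); m <- ncol(w)
  best <- 0
  rec <- function(i, usedCols, acc) {
    if (acc > best) best <<- acc
    if (i > n) return()
    rec(i + 1L, usedCols, acc) # row i unmatched
    for (j in seq_len(m)) {
      if (usedCols[j] || w[i, j] <= 0) next
      usedCols[j] <- TRUE
      rec(i + 1L, usedCols, acc + w[i, j])
      usedCols[j] <- FALSE
    }
  }
  rec(1L, rep(FALSE, m), 0)
  best
}

# canonical string form of a NEP list, for set comparisons
nepKeyStrings <- function(neps) {
  sort(vapply(neps, function(e)
    paste(paste(names(e$items), e$items, sep = ":", collapse = ","),
          format(e$supportTarget, digits = 12),
          format(e$supportBackground, digits = 12), sep = "|"),
    character(1)))
}

writeTempLines <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}
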