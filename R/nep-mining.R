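#' Support of an itemset in a discretized dataset
#'
#' An item is a (feature, bin) pair; an itemset holds at most one item per
#' feature and is contained in an instance when every item matches the
#' instance's bin for that feature. Support is the fraction of instances
#' containing the itemset; the empty itemset has support 1.
#'
#' @param itemset named integer vector of bin indices, names are feature
#'   names (or column indices as characters).
#' @param dataset integer matrix of item vectors (rows = instances, columns
#'   = features).
#' @return support in [0, 1].
#' @export
itemSupport <- function(itemset, dataset) {
  if (!is.matrix(dataset) || nrow(dataset) == 0)
    stop("dataset must be a nonempty matrix")
  if (length(itemset) == 0) return(1)
  cols <- .itemCols(itemset, dataset)
  hit <- rep(TRUE, nrow(dataset))
  for (i in seq_along(itemset))
    hit <- hit & dataset[, cols[i]] == itemset[i]
  mean(hit)
}

.itemCols <- function(itemset, dataset) {
  nm <- names(itemset)
  if (is.null(nm)) stop("itemset must be named by feature")
  cols <- match(nm, colnames(dataset))
  if (anyNA(cols)) cols <- as.integer(nm)
  if (anyNA(cols)) stop("unknown feature in itemset")
  cols
}

.featNames <- function(mat) {
  if (!is.null(colnames(mat))) colnames(mat) else as.character(seq_len(ncol(mat)))
}

.nepKey <- function(items)
  paste(names(items), items, sep = ":", collapse = ",")

.makeNEP <- function(feats, bins, suppT, suppB, featNames) {
  o <- order(feats)
  items <- as.integer(bins[o])
  names(items) <- featNames[feats[o]]
  list(items = items, supportTarget = suppT, supportBackground = suppB)
}

.checkDeltas <- function(delta1, delta2) {
  if (!(delta1 >= 0 && delta2 > delta1 && delta2 <= 1))
    stop("need 0 <= delta1 < delta2 <= 1")
}

.sortNEPs <- function(neps) {
  if (length(neps) == 0) return(neps)
  keys <- vapply(neps, function(e) .nepKey(e$items), character(1))
  neps[order(keys)]
}

#' Mine minimal noise-tolerant emerging patterns (NEPs)
#'
#' An NEP from the background class D1 to the target class D2 is an itemset
#' X with background support at most \code{delta1}, target support at least
#' \code{delta2}, such that no proper subset of X satisfies the background
#' rarity condition (minimality). The miner runs a depth-first search over
#' items ordered by ascending background support, pruning branches whose
#' target support falls below \code{delta2} (support is anti-monotone) and
#' stopping extension once rarity is reached (any superset would be
#' non-minimal). Items from features that take a single bin across both
#' classes are excluded: they occur in every instance and can never
#' discriminate.
#'
#' @param background integer matrix of item vectors for D1.
#' @param target integer matrix of item vectors for D2.
#' @param delta1 maximum background support (rarity threshold).
#' @param delta2 minimum target support (frequency threshold);
#'   \code{delta2 > delta1}.
#' @return list of NEPs, each a list with \code{items} (named integer
#'   vector), \code{supportTarget} and \code{supportBackground}, in a
#'   canonical deterministic order.
#' @seealso \code{\link{bruteForceNEPs}} for the exhaustive reference
#'   implementation used in verification.
#' @export
mineNEPs <- function(background, target, delta1, delta2) {
  .checkDeltas(delta1, delta2)
  if (!is.matrix(background) || nrow(background) == 0 ||
      !is.matrix(target) || nrow(target) == 0)
    stop("both classes must be nonempty matrices")
  nB <- nrow(background); nT <- nrow(target)
  featNames <- .featNames(target)

  feats <- integer(0); bins <- integer(0)
  tRowsList <- list(); bRowsList <- list()
  for (f in seq_len(ncol(target))) {
    if (length(unique(c(background[, f], target[, f]))) < 2) next
    for (b in sort(unique(target[, f]))) {
      tR <- which(target[, f] == b)
      if (length(tR) / nT < delta2) next
      feats <- c(feats, f); bins <- c(bins, b)
      tRowsList[[length(feats)]] <- tR
      bRowsList[[length(feats)]] <- which(background[, f] == b)
    }
  }
  K <- length(feats)
  if (K == 0) return(list())
  ord <- order(vapply(bRowsList, length, integer(1)))
  feats <- feats[ord]; bins <- bins[ord]
  tRowsList <- tRowsList[ord]; bRowsList <- bRowsList[ord]

  results <- list()
  bgSupportOf <- function(sel) { # support in D1 of the itemset at indices sel
    if (length(sel) == 0) return(1)
    length(Reduce(intersect, bRowsList[sel])) / nB
  }
  isMinimal <- function(sel) {
    if (length(sel) == 1) return(TRUE) # empty subset has support 1 > delta1
    for (d in seq_along(sel))
      if (bgSupportOf(sel[-d]) <= delta1) return(FALSE)
    TRUE
  }
  recurse <- function(sel, tRows, bRows, nextIdx) {
    if (nextIdx > K) return()
    usedFeats <- feats[sel]
    for (k in nextIdx:K) {
      if (feats[k] %in% usedFeats) next
      tR <- intersect(tRows, tRowsList[[k]])
      if (length(tR) / nT < delta2) next
      bR <- intersect(bRows, bRowsList[[k]])
      newSel <- c(sel, k)
      if (length(bR) / nB <= delta1) {
        if (isMinimal(newSel))
          results[[length(results) + 1L]] <<-
            .makeNEP(feats[newSel], bins[newSel],
                     length(tR) / nT, length(bR) / nB, featNames)
      } else {
        recurse(newSel, tR, bR, k + 1L)
      }
    }
  }
  recurse(integer(0), seq_len(nT), seq_len(nB), 1L)
  .sortNEPs(results)
}

#' Exhaustive NEP enumeration (verification oracle)
#'
#' Enumerates every itemset over the items occurring in the target class
#' (at most one item per feature) and applies the NEP definition literally:
#' background support at most \code{delta1}, target support at least
#' \code{delta2}, and no proper subset background-rare. Because support is
#' anti-monotone, checking the maximal proper subsets suffices for the
#' minimality clause. Intended for testing on small instances only.
#'
#' @inheritParams mineNEPs
#' @param maxItems guard on the item-universe size (default 24).
#' @return list of NEPs in the same canonical order as
#'   \code{\link{mineNEPs}}.
#' @export
bruteForceNEPs <- function(background, target, delta1, delta2,
                           maxItems = 24L) {
  .checkDeltas(delta1, delta2)
  if (!is.matrix(background) || nrow(background) == 0 ||
      !is.matrix(target) || nrow(target) == 0)
    stop("both classes must be nonempty matrices")
  nB <- nrow(background); nT <- nrow(target)
  featNames <- .featNames(target)

  # universe: items occurring in the target class
  feats <- integer(0); bins <- integer(0)
  tRowsList <- list(); bRowsList <- list()
  for (f in seq_len(ncol(target))) {
    for (b in sort(unique(target[, f]))) {
      feats <- c(feats, f); bins <- c(bins, b)
      tRowsList[[length(feats)]] <- which(target[, f] == b)
      bRowsList[[length(feats)]] <- which(background[, f] == b)
    }
  }
  if (length(feats) > maxItems)
    stop("item universe too large (", length(feats), " > ", maxItems,
         "); this oracle is for small test instances only")

  # enumerate all itemsets (<=1 item per feature), depth-first by feature
  supp <- new.env(parent = emptyenv()) # key -> c(suppB, suppT)
  sets <- list()
  byFeat <- split(seq_along(feats), feats[seq_along(feats)])
  featIds <- as.integer(names(byFeat))
  enum <- function(fi, sel, tRows, bRows) {
    if (fi > length(featIds)) {
      if (length(sel) > 0) {
        key <- .nepKey(.makeNEP(feats[sel], bins[sel], 0, 0, featNames)$items)
        assign(key, c(length(bRows) / nB, length(tRows) / nT), envir = supp)
        sets[[length(sets) + 1L]] <<- sel
      }
      return()
    }
    enum(fi + 1L, sel, tRows, bRows) # feature absent
    for (k in byFeat[[fi]])
      enum(fi + 1L, c(sel, k),
           intersect(tRows, tRowsList[[k]]), intersect(bRows, bRowsList[[k]]))
  }
  enum(1L, integer(0), seq_len(nT), seq_len(nB))

  results <- list()
  for (sel in sets) {
    key <- .nepKey(.makeNEP(feats[sel], bins[sel], 0, 0, featNames)$items)
    s <- get(key, envir = supp)
    if (s[1] > delta1 || s[2] < delta2) next
    minimal <- TRUE
    if (length(sel) > 1) {
      for (d in seq_along(sel)) {
        sub <- sel[-d]
        skey <- .nepKey(.makeNEP(feats[sub], bins[sub], 0, 0,
                                 featNames)$items)
        if (get(skey, envir = supp)[1] <= delta1) { minimal <- FALSE; break }
      }
    }
    if (minimal)
      results[[length(results) + 1L]] <-
        .makeNEP(feats[sel], bins[sel], s[2], s[1], featNames)
  }
  .sortNEPs(results)
}

#' Mine NEPs of both classes
#'
#' EP(Dp) is mined with the negatives as background and the positives as
#' target; EP(Dn) the other way round.
#'
#' @param dp integer matrix of positive-class item vectors.
#' @param dn integer matrix of negative-class item vectors.
#' @inheritParams mineNEPs
#' @return list with elements \code{epPos} and \code{epNeg}.
#' @export
mineBothClasses <- function(dp, dn, delta1, delta2) {
  list(epPos = mineNEPs(dn, dp, delta1, delta2),
       epNeg = mineNEPs(dp, dn, delta1, delta2))
}
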