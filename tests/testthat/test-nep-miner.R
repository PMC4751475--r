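asItemMatrix <- function(rows) {
  m <- do.call(rbind, rows)
  colnames(m) <- paste0("F", seq_len(ncol(m)))
  m
}

test_that("itemset support counts containment correctly", {
  d <- asItemMatrix(list(c(1, 0), c(1, 2), c(1, 1), c(1, 0)))
  expect_equal(itemSupport(c(F1 = 1), d), 1)
  expect_equal(itemSupport(c(F2 = 0), d), 0.5)
  expect_equal(itemSupport(c(F1 = 1, F2 = 0), d), 0.5)
  expect_equal(itemSupport(setNames(integer(0), character(0)), d), 1)
  expect_equal(itemSupport(c(F1 = 9), d), 0)
  expect_error(itemSupport(c(F1 = 1), matrix(integer(0), 0, 2)), "nonempty")
})

test_that("single discriminating item is mined as a minimal NEP", {
  target <- asItemMatrix(list(c(0, 1), c(0, 2), c(0, 1), c(0, 0)))
  background <- asItemMatrix(list(c(1, 1), c(2, 2), c(1, 1), c(2, 0)))
  neps <- mineNEPs(background, target, delta1 = 0.1, delta2 = 0.7)
  expect_length(neps, 1)
  expect_equal(neps[[1]]$items, c(F1 = 0L))
  expect_equal(neps[[1]]$supportTarget, 1)
  expect_equal(neps[[1]]$supportBackground, 0)
})

test_that("identical classes admit no NEP", {
  d <- asItemMatrix(list(c(0, 1), c(1, 0), c(0, 0), c(1, 1)))
  expect_length(mineNEPs(d, d, delta1 = 0.1, delta2 = 0.7), 0)
  expect_error(mineNEPs(d, d, delta1 = 0.7, delta2 = 0.2), "delta")
})

test_that("a rare pair can be an NEP while its items are not", {
  # build 20-row classes: items F1=0 and F2=0 each common in background
  # (support 0.5) but jointly rare (0.05); both frequent together in target
  bg <- vector("list", 20)
  for (i in 1:20) {
    bg[[i]] <- if (i == 1) c(0, 0, 9)
    else if (i <= 10) c(0, 1, 9) else c(1, 0, 9)
  }
  set.seed(4)
  tg <- replicate(20, c(0, 0, sample(0:1, 1)), simplify = FALSE)
  bg <- asItemMatrix(bg); tg <- asItemMatrix(tg)
  neps <- mineNEPs(bg, tg, delta1 = 0.1, delta2 = 0.7)
  keys <- vapply(neps, function(e)
    paste(names(e$items), e$items, sep = ":", collapse = ","), character(1))
  expect_true("F1:0,F2:0" %in% keys)
  expect_false("F1:0" %in% keys)
  expect_false("F2:0" %in% keys)
  pair <- neps[[match("F1:0,F2:0", keys)]]
  expect_equal(pair$supportBackground, 0.05)
  expect_equal(pair$supportTarget, 1)
  # oracle agrees in full
  expect_identical(nepKeyStrings(neps),
                   nepKeyStrings(bruteForceNEPs(bg, tg, 0.1, 0.7)))
})

test_that("oracle limit cases behave as the definition dictates", {
  tg <- asItemMatrix(list(c(0, 0), c(0, 0), c(0, 1)))
  bg <- asItemMatrix(list(c(0, 1), c(1, 1), c(1, 0)))
  # delta1 = 0: only itemsets absent from the background qualify
  neps0 <- bruteForceNEPs(bg, tg, delta1 = 0, delta2 = 0.6)
  expect_true(all(vapply(neps0, function(e) e$supportBackground,
                         numeric(1)) == 0))
  # delta2 = 1: only itemsets present in every target vector qualify
  neps1 <- bruteForceNEPs(bg, tg, delta1 = 0.4, delta2 = 1)
  expect_true(all(vapply(neps1, function(e) e$supportTarget,
                         numeric(1)) == 1))
  expect_error(bruteForceNEPs(bg, tg, 0.1, 0.7, maxItems = 2), "universe")
})

test_that("miner and oracle agree on random small instances", {
  for (seed in 1:40) {
    inst <- randomItemInstance(seed)
    a <- mineNEPs(inst$background, inst$target, inst$delta1, inst$delta2)
    b <- bruteForceNEPs(inst$background, inst$target, inst$delta1,
                        inst$delta2)
    expect_identical(nepKeyStrings(a), nepKeyStrings(b), label = paste0(
      "miner vs oracle, instance ", seed))
  }
})

test_that("support is anti-monotone under itemset growth", {
  set.seed(21)
  for (rep in 1:30) {
    inst <- randomItemInstance(rep + 100)
    d <- inst$target
    nf <- ncol(d)
    k <- sample(2:nf, 1)
    feats <- sample(colnames(d), k)
    bins <- vapply(feats, function(f) sample(d[, f], 1), numeric(1))
    big <- setNames(as.integer(bins), feats)
    small <- big[seq_len(k - 1)]
    expect_gte(itemSupport(small, d), itemSupport(big, d))
  }
})

test_that("no mined NEP is a superset of another (minimality audit)", {
  auditNoContainment <- function(neps) {
    for (i in seq_along(neps)) for (j in seq_along(neps)) {
      if (i == j) next
      a <- neps[[i]]$items; b <- neps[[j]]$items
      contained <- length(a) < length(b) &&
        all(names(a) %in% names(b)) &&
        all(b[names(a)] == a)
      expect_false(contained)
    }
  }
  # constructed instance with two guaranteed single-item NEPs
  tg <- asItemMatrix(list(c(0, 0), c(0, 0), c(0, 0)))
  bg <- asItemMatrix(list(c(1, 1), c(1, 1), c(1, 1)))
  neps <- mineNEPs(bg, tg, delta1 = 0.1, delta2 = 0.7)
  expect_length(neps, 2)
  auditNoContainment(neps)
  # plus random instances
  for (seed in c(3, 17, 42, 55, 61)) {
    inst <- randomItemInstance(seed, maxFeat = 5, maxBins = 3)
    auditNoContainment(mineNEPs(inst$background, inst$target, inst$delta1,
                                inst$delta2))
  }
})

test_that("relaxing thresholds never shrinks the pre-minimality region", {
  # conditions 1-2 (before the minimality clause) define a constraint region
  # monotone in delta1 (raising) and delta2 (lowering); enumerate directly
  inst <- randomItemInstance(8, maxFeat = 4, maxBins = 3, maxRows = 20)
  bg <- inst$background; tg <- inst$target
  universe <- do.call(expand.grid, c(lapply(seq_len(ncol(tg)), function(f)
    c(NA, sort(unique(tg[, f])))), KEEP.OUT.ATTRS = FALSE))
  region <- function(d1, d2) {
    ok <- apply(universe, 1, function(row) {
      its <- setNames(as.integer(row[!is.na(row)]),
                      colnames(tg)[!is.na(row)])
      if (length(its) == 0) return(FALSE)
      itemSupport(its, bg) <= d1 && itemSupport(its, tg) >= d2
    })
    which(ok)
  }
  strict <- region(0.05, 0.9)
  relaxed <- region(0.15, 0.7)
  expect_true(all(strict %in% relaxed))
})

test_that("mining both classes is symmetric and finds printed-style EPs", {
  # positive class concentrated (an item in ~90% of positives, 0% of
  # negatives) must surface in EP(Dp)
  set.seed(6)
  dp <- asItemMatrix(c(replicate(9, c(5, 1), simplify = FALSE),
                       list(c(0, 1))))
  dn <- asItemMatrix(replicate(20, c(sample(0:4, 1), sample(0:1, 1)),
                               simplify = FALSE))
  both <- mineBothClasses(dp, dn, delta1 = 0.1, delta2 = 0.7)
  posKeys <- vapply(both$epPos, function(e)
    paste(names(e$items), e$items, sep = ":", collapse = ","), character(1))
  expect_true("F1:5" %in% posKeys)
  sup <- both$epPos[[match("F1:5", posKeys)]]
  expect_equal(sup$supportTarget, 0.9)
  expect_equal(sup$supportBackground, 0)

  swapped <- mineBothClasses(dn, dp, delta1 = 0.1, delta2 = 0.7)
  expect_identical(nepKeyStrings(both$epPos), nepKeyStrings(swapped$epNeg))
  expect_identical(nepKeyStrings(both$epNeg), nepKeyStrings(swapped$epPos))
})
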