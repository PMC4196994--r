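# Proposal mechanics, Hastings correction, and the compiled chain.

test_that("initState is the all-coil single block", {
  s1 <- initState(1)
  expect_identical(blockTypes(s1@annotation), "C")
  s29 <- initState(29)
  expect_identical(blockLengths(s29@annotation), 29L)
  expect_identical(nBlocks(s29@annotation), 1L)
})

test_that("only switch and split are drawable from a single block", {
  st <- initState(8)
  set.seed(2)
  kinds <- replicate(300, proposeMove(st)$kind)
  expect_setequal(unique(kinds), c("switch", "split"))
})

test_that("split and merge form a reversible pair", {
  set.seed(3)
  st <- initState(4)
  found <- FALSE
  for (i in 1:200) {
    pr <- proposeMove(st)
    if (pr$kind != "split") next
    cand <- pr$candidate
    expect_identical(sum(blockLengths(cand)), 4L)
    expect_identical(nBlocks(cand), 2L)
    expect_identical(blockTypes(cand)[1], "C")  # left keeps its type
    expect_true(is.finite(pr$logQRev))          # the reverse merge exists
    # a merge on the candidate restores the original state
    merged <- canonicalizeAnnotation(
      BlockAnnotation(blockTypes(cand)[1],
                      sum(blockLengths(cand))))
    expect_identical(blocksToLinear(merged) == "CCCC",
                     blockTypes(cand)[1] == "C")
    found <- TRUE
  }
  expect_true(found)
})

test_that("proposal frequencies match the uniform scheme", {
  # frozen 3-block state: all four kinds feasible
  st <- new("ChainState",
            annotation = BlockAnnotation(c("C", "H", "C"), c(2, 4, 2)),
            logLik = NA_real_, logPrior = NA_real_)
  set.seed(11)
  n <- 40000
  kinds <- character(n)
  switchBlock <- integer(0)
  for (i in seq_len(n)) {
    pr <- proposeMove(st)
    kinds[[i]] <- pr$kind
    if (pr$kind == "switch") {
      changed <- which(blockTypes(pr$candidate) !=
                         blockTypes(st@annotation))
      switchBlock <- c(switchBlock, changed)
    }
  }
  tab <- table(kinds)
  for (k in c("switch", "boundary", "split", "merge")) {
    p <- unname(tab[k]) / n
    se <- sqrt(0.25 * 0.75 / n)
    expect_lt(abs(p - 0.25), 3 * se)
  }
  # within switch, the block is uniform over the three blocks
  tb <- table(factor(switchBlock, levels = 1:3))
  pB <- as.vector(tb) / length(switchBlock)
  seB <- sqrt((1 / 3) * (2 / 3) / length(switchBlock))
  expect_true(all(abs(pB - 1 / 3) < 3.5 * seB))
})

test_that("local Hastings ratios equal full recomputation", {
  m <- fixtureModel
  set.seed(13)
  s <- fixtureCorpus$sequence[[3]]
  s <- substr(s, 1, 10)
  prof <- corruptMsaProfile(substr(fixtureCorpus$structure[[3]], 1, 10),
                            depth = 10, errorRate = 0.2)
  nChecked <- 0
  st <- scoreState(initState(10), m, s)
  stMsa <- scoreState(initState(10), m, s, prior = "msa", profile = prof)
  for (i in 1:1000) {
    pr <- proposeMove(st)
    lc <- hastingsLogRatio(m, s, st, pr, method = "local")
    fu <- hastingsLogRatio(m, s, st, pr, method = "full")
    if (is.finite(lc) || is.finite(fu)) {
      expect_equal(lc, fu, tolerance = 1e-9)
      nChecked <- nChecked + 1
    } else expect_identical(is.finite(lc), is.finite(fu))
    prM <- proposeMove(stMsa)
    lcM <- hastingsLogRatio(m, s, stMsa, prM, prior = "msa",
                            profile = prof, method = "local")
    fuM <- hastingsLogRatio(m, s, stMsa, prM, prior = "msa",
                            profile = prof, method = "full")
    if (is.finite(lcM) || is.finite(fuM)) expect_equal(lcM, fuM,
                                                       tolerance = 1e-9)
    # advance both chains so transitions cover varied states
    st <- acceptMove(st, pr, m, s)$state
    stMsa <- acceptMove(stMsa, prM, m, s, prior = "msa",
                        profile = prof)$state
  }
  expect_gt(nChecked, 200)
})

test_that("flat posteriors accept valid switch moves with probability one", {
  m0 <- emptyModel()
  s <- "AMKVGAMK"
  st <- scoreState(new("ChainState",
                       annotation = BlockAnnotation(c("C", "T", "C"),
                                                    c(2, 3, 3)),
                       logLik = NA_real_, logPrior = NA_real_), m0, s)
  set.seed(17)
  for (i in 1:200) {
    pr <- proposeMove(st)
    if (pr$kind != "switch") next
    if (!isTRUE(c(validateAnnotation(pr$candidate)))) next
    expect_equal(hastingsLogRatio(m0, s, st, pr, method = "local"), 0,
                 tolerance = 1e-12)
  }
})

test_that("invalid candidates are always rejected", {
  m <- fixtureModel
  s <- "AMKVG"
  st <- scoreState(initState(5), m, s)
  set.seed(19)
  for (i in 1:100) {
    pr <- proposeMove(st)
    if (isTRUE(c(validateAnnotation(pr$candidate)))) next
    res <- acceptMove(st, pr, m, s)
    expect_false(res$accepted)
    expect_identical(res$logRatio, -Inf)
  }
})

test_that("fixed seeds give identical posterior summaries", {
  m <- fixtureModel
  s <- "AMKVGAMKVG"
  a <- runChain(m, s, nProposals = 2e4, burnin = 1e3, seed = 5,
                trackStates = TRUE, keepEvery = 500)
  b <- runChain(m, s, nProposals = 2e4, burnin = 1e3, seed = 5,
                trackStates = TRUE, keepEvery = 500)
  expect_identical(marginals(a), marginals(b))
  expect_identical(a@trace, b@trace)
  expect_identical(a@stateFreq, b@stateFreq)
  expect_identical(blocksToLinear(mapEstimate(a)),
                   blocksToLinear(mapEstimate(b)))
})

test_that("chain marginals are proper and states stay valid", {
  m <- fixtureModel
  s <- "AMKVGAMKVG"
  sm <- runChain(m, s, nProposals = 3e4, burnin = 2e3, seed = 6,
                 trackStates = TRUE, keepEvery = 100)
  expect_equal(rowSums(marginals(sm)), rep(1, 10), tolerance = 1e-9)
  # every visited state is valid (same-type adjacency allowed)
  for (ann in sm@samples)
    expect_true(c(validateAnnotation(ann)))
  expect_gt(length(sm@stateFreq), 1)
  expect_equal(sum(sm@stateFreq), 1, tolerance = 1e-9)
  # the MAP log posterior matches the trace maximum (thin = 1)
  expect_equal(sm@map$logPost, max(sm@trace), tolerance = 1e-9)
})

test_that("independent chains from different starts agree", {
  m <- fixtureModel
  set.seed(23)
  ann <- sampleStructure(fixtureSpec, 7)
  s <- sampleSequence(fixtureSpec, ann)
  init2 <- BlockAnnotation(c("C", "T", "C"), c(2, 3, 2))
  a <- runChain(m, s, nProposals = 3e5, burnin = 1e4, seed = 7)
  b <- runChain(m, s, nProposals = 3e5, burnin = 1e4, seed = 8,
                init = init2)
  expect_lt(max(abs(marginals(a) - marginals(b))), 0.03)
})

test_that("counting infeasible kinds as rejections is supported", {
  m <- fixtureModel
  s <- "AMKVG"
  sm <- runChain(m, s, nProposals = 1e4, burnin = 1e3, seed = 9,
                 resampleInfeasible = FALSE)
  d <- diagnostics(sm)
  # from near-single-block states, boundary/merge draws are often
  # infeasible and must be counted
  expect_gt(d$nInfeasibleRejected, 0)
  expect_equal(rowSums(marginals(sm)), rep(1, 5), tolerance = 1e-9)
})
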