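# MAP/MP estimators, block-count posteriors and margin statistics.

# a sharply informative profile concentrates the posterior on the truth
sharpSummary <- function(truth, seed = 31, nProposals = 5e4) {
  s <- sampleSequence(fixtureSpec, linearToBlocks(truth))
  prof <- corruptMsaProfile(truth, depth = 200, errorRate = 0)
  runChain(fixtureModel, s, prior = "msa", profile = prof,
           nProposals = nProposals, burnin = 5e3, seed = seed,
           keepEvery = 100)
}

test_that("a concentrated posterior pins MAP and MP to the same state", {
  set.seed(31)
  truth <- "CCHHHHCCC"
  sm <- sharpSummary(truth)
  expect_identical(blocksToLinear(mapEstimate(sm)), truth)
  expect_identical(mpEstimate(sm), truth)
  bc <- blockCountPosterior(sm)
  expect_gt(bc$total[["3"]], 0.95)  # essentially a point mass
})

test_that("the MAP sample dominates every retained log posterior", {
  m <- fixtureModel
  sm <- runChain(m, "AMKVGAMKVG", nProposals = 2e4, burnin = 2e3,
                 seed = 33)
  expect_gte(sm@map$logPost, max(sm@trace))
})

test_that("mpEstimate takes the per-position argmax with fixed ties", {
  marg <- rbind(c(0.1, 0.2, 0.3, 0.4),
                c(0.4, 0.3, 0.2, 0.1),
                c(0.25, 0.25, 0.25, 0.25),
                c(0.4, 0.4, 0.1, 0.1))
  colnames(marg) <- c("H", "E", "T", "C")
  # ties prefer C > T > E > H
  expect_identical(mpEstimate(marg), "CHCE")
})

test_that("block-count posteriors are normalized and additive in the mean", {
  sm <- runChain(fixtureModel, "AMKVGAMKVG", nProposals = 3e4,
                 burnin = 3e3, seed = 35)
  bc <- blockCountPosterior(sm)
  expect_equal(sum(bc$total), 1, tolerance = 1e-9)
  for (ty in names(bc$byType))
    expect_equal(sum(bc$byType[[ty]]), 1, tolerance = 1e-9)
  meanOf <- function(v) sum(as.numeric(names(v)) * v)
  expect_equal(sum(vapply(bc$byType, meanOf, numeric(1))),
               meanOf(bc$total), tolerance = 1e-9)
})

test_that("MAP matches the exact argmax on concentrated toy posteriors", {
  set.seed(37)
  hits <- 0
  for (run in 1:10) {
    ann <- sampleStructure(fixtureSpec, 7)
    truth <- blocksToLinear(ann)
    s <- sampleSequence(fixtureSpec, ann)
    prof <- corruptMsaProfile(truth, depth = 50, errorRate = 0.05)
    post <- exactPosterior(fixtureModel, s, prior = "msa", profile = prof)
    exactMode <- post$keys[[which.max(post$prob)]]
    sm <- runChain(fixtureModel, s, prior = "msa", profile = prof,
                   nProposals = 5e4, burnin = 5e3, seed = 100 + run)
    a <- sm@map$annotation
    if (paste0(blockTypes(a), blockLengths(a), collapse = "") == exactMode)
      hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("margin statistics reproduce hand-computed values", {
  # one-hot and correct: margin 1, sd 0
  marg1 <- diag(4)[c(1, 1, 2, 2, 3, 3, 4, 4), ]
  colnames(marg1) <- c("H", "E", "T", "C")
  st <- marginStatistics(marg1, prediction = "HHEETTCC", truth = "HHEETTCC")
  ok <- st[st$outcome == "correct" & st$n > 0, ]
  expect_equal(ok$mean, rep(1, 4))
  expect_equal(ok$sd, rep(0, 4))
  # uniform marginals: all margins zero
  margU <- matrix(0.25, 3, 4, dimnames = list(NULL, c("H", "E", "T", "C")))
  stU <- marginStatistics(margU, prediction = "HHH", truth = "HEC")
  expect_equal(stU$mean[stU$n > 0], rep(0, sum(stU$n > 0)))
  # hand-built 6-position example
  marg6 <- rbind(c(0.7, 0.1, 0.1, 0.1),   # pred H, truth H: 0.7 - 0.1
                 c(0.5, 0.3, 0.1, 0.1),   # pred H, truth H: 0.5 - 0.3
                 c(0.6, 0.2, 0.1, 0.1),   # pred H, truth E (wrong): 0.6 - 0.2
                 c(0.1, 0.2, 0.3, 0.4),   # pred C, truth C: 0.4 - 0.3
                 c(0.1, 0.1, 0.2, 0.6),   # pred C, truth T (wrong): 0.6 - 0.2
                 c(0.2, 0.2, 0.2, 0.4))   # pred C, truth C: 0.4 - 0.2
  colnames(marg6) <- c("H", "E", "T", "C")
  st6 <- marginStatistics(marg6, prediction = "HHHCCC", truth = "HHECTC")
  get <- function(state, outcome)
    st6[st6$state == state & st6$outcome == outcome, ]
  expect_equal(get("H", "correct")$mean, mean(c(0.6, 0.2)))
  expect_equal(get("E", "wrong")$mean, 0.4)
  expect_equal(get("C", "correct")$mean, mean(c(0.1, 0.2)))
  expect_equal(get("T", "wrong")$mean, 0.4)
  expect_identical(get("E", "correct")$n, 0L)
})
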