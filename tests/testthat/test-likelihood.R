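# Block and joint log-likelihoods, the helix mixture, and the
# per-segment matrix cache.

test_that("an untrained model is uniform over residues", {
  m0 <- emptyModel()
  for (ty in c("H", "E", "T", "C"))
    for (len in c(1, 3, 5, 8)) {
      r <- paste(rep("K", len), collapse = "")
      expect_equal(blockLogLik(m0, r, ty), len * log(1 / 20),
                   tolerance = 1e-12)
    }
})

test_that("helix mixture with identical components collapses to one", {
  # mirror-symmetric tables: untrained, so forward == backward exactly
  m0 <- emptyModel()
  mW <- emptyModel(mixtureWeight = 0.83)
  expect_equal(blockLogLik(m0, "MKVLA", "H"), blockLogLik(mW, "MKVLA", "H"),
               tolerance = 1e-12)
})

test_that("strand likelihood matches hand-computed smoothed products", {
  corpus <- data.frame(id = c("a", "b"),
                       sequence = c("AMKVG", "AMCVG"),
                       structure = c("CEEEC", "CEEEC"))
  m <- trainModel(corpus)
  # strand blocks: MKV and MCV. Slot tables (by independent count):
  #  slot1 (unconditional): M twice          -> p(M) = (2+1)/(2+20)
  #  slot2 (unconditional): K once, C once   -> p(K) = (1+1)/(2+20)
  #  slot3 (context -2 = M): V twice         -> p(V|M) = (2+1)/(2+20)
  byHand <- log(3 / 22) + log(2 / 22) + log(3 / 22)
  expect_equal(blockLogLik(m, "MKV", "E"), byHand, tolerance = 1e-12)
})

test_that("totalLogLik factorizes over blocks with boundary resets", {
  m <- fixtureModel
  s <- "AMKVGAMKVG"
  one <- totalLogLik(m, s, BlockAnnotation("C", 10))
  expect_equal(one, blockLogLik(m, s, "C"), tolerance = 1e-12)
  # conditioning resets at block boundaries: a split coil run differs
  split2 <- totalLogLik(m, s, BlockAnnotation(c("C", "C"), c(5, 5)))
  expect_false(isTRUE(all.equal(one, split2)))
  expect_error(totalLogLik(m, s, BlockAnnotation("C", 9)), "covers")
})

test_that("exp(totalLogLik) sums to one over all sequences (L = 2)", {
  m <- fixtureModel
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  seqs <- as.vector(outer(aa, aa, paste0))
  for (ann in list(BlockAnnotation("C", 2),
                   BlockAnnotation(c("C", "C"), c(1, 1)),
                   BlockAnnotation("H", 2))) {
    tot <- sum(vapply(seqs, function(s) exp(totalLogLik(m, s, ann)),
                      numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-9)
  }
})

test_that("helix log-likelihood lies between its mixture components", {
  mF <- fixtureModel; mF@mixtureWeight <- 1
  mB <- fixtureModel; mB@mixtureWeight <- 0
  set.seed(3)
  for (rep in 1:20) {
    len <- sample(3:9, 1)
    r <- paste(sample(c("A","L","K","V","E","G"), len, replace = TRUE),
               collapse = "")
    f <- blockLogLik(mF, r, "H")
    b <- blockLogLik(mB, r, "H")
    mix <- blockLogLik(fixtureModel, r, "H")
    expect_gte(mix, min(f, b) - 1e-12)
    expect_lte(mix, max(f, b) + 1e-12)
  }
})

test_that("log-space evaluation does not underflow on long chains", {
  m <- fixtureModel
  set.seed(5)
  r <- paste(sample(c("A","L","K","V","E","G","S","T"), 2000,
                    replace = TRUE), collapse = "")
  for (ty in c("H", "E", "T", "C"))
    expect_true(is.finite(blockLogLik(m, r, ty)))
  ann <- BlockAnnotation(c("C", "H", "C", "E", "C"),
                         c(500, 400, 500, 300, 300))
  expect_true(is.finite(totalLogLik(m, r, ann)))
})

test_that("segment matrices agree with direct block evaluation", {
  m <- fixtureModel
  set.seed(6)
  s <- paste(sample(c("A","L","K","V","E","G","M","Y"), 12,
                    replace = TRUE), collapse = "")
  seg <- segmentLogLik(m, s)
  for (ty in c("H", "E", "T", "C"))
    for (st in 1:12)
      for (en in st:12)
        expect_equal(seg[[ty]][st, en],
                     blockLogLik(m, substr(s, st, en), ty),
                     tolerance = 1e-10,
                     label = sprintf("%s[%d,%d]", ty, st, en))
})

test_that("unknown residues emit flat probabilities and back off contexts", {
  m <- fixtureModel
  # emission of X itself contributes exactly log(1/20)
  expect_equal(blockLogLik(m, "X", "C"), log(1 / 20), tolerance = 1e-12)
  # a context containing X backs off but stays finite
  expect_true(is.finite(blockLogLik(m, "AXKVA", "H")))
})
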