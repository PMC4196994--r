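# Block/linear conversions, canonicalization and the hard-constraint
# validity predicate.

test_that("blocksToLinear expands blocks by concatenation", {
  expect_identical(blocksToLinear(BlockAnnotation("C", 1)), "C")
  expect_identical(blocksToLinear(BlockAnnotation(c("C", "H", "C"),
                                                  c(1, 3, 1))), "CHHHC")
  expect_error(BlockAnnotation(character(), integer()),
               "at least one block")
})

test_that("linearToBlocks run-length encodes state strings", {
  a <- linearToBlocks("CHHHC")
  expect_identical(blockTypes(a), c("C", "H", "C"))
  expect_identical(blockLengths(a), c(1L, 3L, 1L))
  expect_identical(blockTypes(linearToBlocks("CCCC")), "C")
  b <- linearToBlocks("CEEETTTC")
  expect_identical(blockTypes(b), c("C", "E", "T", "C"))
  expect_identical(blockLengths(b), c(1L, 3L, 3L, 1L))
  expect_error(linearToBlocks("CHXZC"), "outside")
  expect_error(linearToBlocks(""), "non-empty")
})

test_that("conversions invert each other exhaustively for short strings", {
  for (L in 1:6) {
    grids <- do.call(expand.grid, rep(list(c("H", "E", "T", "C")), L))
    strs <- do.call(paste0, grids)
    for (s in strs)
      expect_identical(blocksToLinear(linearToBlocks(s)), s)
  }
})

test_that("round trip through linear form canonicalizes annotations", {
  set.seed(1)
  for (rep in 1:200) {
    L <- sample(1:12, 1)
    M <- sample(1:min(4L, L), 1)
    lens <- as.integer(tabulate(sample.int(M, L - M, replace = TRUE),
                                nbins = M)) + 1L
    ann <- BlockAnnotation(sample(c("H", "E", "T", "C"), M, replace = TRUE),
                           lens)
    rt <- linearToBlocks(blocksToLinear(ann))
    can <- canonicalizeAnnotation(ann)
    expect_identical(blockTypes(rt), blockTypes(can))
    expect_identical(blockLengths(rt), blockLengths(can))
    # canonicalization never changes the linear image
    expect_identical(blocksToLinear(can), blocksToLinear(ann))
  }
})

test_that("canonicalizeAnnotation merges same-type neighbours only", {
  a <- canonicalizeAnnotation(BlockAnnotation(c("C", "C"), c(1, 3)))
  expect_identical(blockTypes(a), "C")
  expect_identical(blockLengths(a), 4L)
  b <- BlockAnnotation(c("C", "H", "C"), c(1, 3, 1))
  expect_identical(canonicalizeAnnotation(b), b)
})

test_that("validateAnnotation flags each printed rule", {
  cs <- defaultConstraints()
  expect_true(c(validateAnnotation(BlockAnnotation("C", 1), cs)))
  v <- validateAnnotation(BlockAnnotation("H", 3), cs)
  expect_false(c(v))
  expect_match(attr(v, "violations"), "terminal", all = TRUE)
  v <- validateAnnotation(BlockAnnotation(c("C", "H", "C"), c(1, 2, 1)), cs)
  expect_false(c(v))
  expect_match(attr(v, "violations"), "min-length", all = TRUE)
  v <- validateAnnotation(BlockAnnotation(c("C", "H", "E", "C"),
                                          c(1, 3, 3, 1)), cs)
  expect_false(c(v))
  expect_match(attr(v, "violations"), "adjacency", all = TRUE)
})

test_that("validateAnnotation agrees with an independent brute-force checker", {
  # direct transcription of the six conditions, coded independently
  bruteValid <- function(ty, len) {
    M <- length(ty)
    if (ty[1] != "C" || ty[M] != "C") return(FALSE)
    for (i in seq_len(M - 1)) {
      if (ty[i] == "H" && ty[i + 1] == "E") return(FALSE)
      if (ty[i] == "E" && ty[i + 1] == "H") return(FALSE)
    }
    for (i in seq_len(M)) {
      if (ty[i] == "H" && len[i] < 3) return(FALSE)
      if (ty[i] == "E" && len[i] < 3) return(FALSE)
      if (ty[i] == "T" && len[i] < 3) return(FALSE)
    }
    TRUE
  }
  cs <- defaultConstraints()
  # all typed compositions of total length <= 6
  compositions <- function(L) {
    if (L == 0) return(list(integer()))
    out <- list()
    for (first in 1:L)
      for (rest in compositions(L - first))
        out[[length(out) + 1L]] <- c(first, rest)
    out
  }
  for (L in 1:6) {
    for (lens in compositions(L)) {
      M <- length(lens)
      grids <- do.call(expand.grid,
                       c(rep(list(c("H", "E", "T", "C")), M),
                         stringsAsFactors = FALSE))
      for (r in seq_len(nrow(grids))) {
        ty <- as.character(grids[r, ])
        expect_identical(
          c(validateAnnotation(BlockAnnotation(ty, lens), cs)),
          bruteValid(ty, lens))
      }
    }
  }
})

test_that("constraint sets are data and can be relaxed", {
  loose <- ConstraintSet(minLengths = c(H = 1, E = 1, T = 1, C = 1),
                         forbiddenAdjacency = NULL,
                         terminalType = NA)
  expect_true(c(validateAnnotation(BlockAnnotation("H", 1), loose)))
  expect_true(c(validateAnnotation(BlockAnnotation(c("H", "E"), c(1, 1)),
                                   loose)))
})
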