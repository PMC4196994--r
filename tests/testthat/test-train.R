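# Count accumulation and Dirichlet-multinomial smoothing.

test_that("training counts anchor helix slots at both termini", {
  m <- trainModel(data.frame(id = "a", sequence = "MKVLA",
                             structure = "CHHHC"))
  # the helix block is KVL: forward slot 1 sees K
  expect_identical(m@tables$H_fwd[[1]]$counts[["."]][[match("K", c(
    "A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S","T","V","W","Y"))]],
    1L)
  # backward slot 1 anchors at the C-terminal residue L
  expect_equal(sum(m@tables$H_bwd[[1]]$counts[["."]]), 1L)
  expect_identical(which(m@tables$H_bwd[[1]]$counts[["."]] == 1L),
                   match("L", c("A","C","D","E","F","G","H","I","K","L",
                                "M","N","P","Q","R","S","T","V","W","Y")))
})

test_that("slot-1 coil totals equal the number of coil blocks", {
  m <- fixtureModel
  # independent recount from the raw structure strings
  nCoil <- sum(vapply(fixtureCorpus$structure, function(s) {
    r <- rle(strsplit(s, "")[[1]])
    sum(r$values == "C")
  }, numeric(1)))
  expect_identical(sum(m@tables$C[[1]]$counts[["."]]), as.integer(nCoil))
  expect_identical(m@meta$blockCounts[["C"]], as.integer(nCoil))
})

test_that("per-slot totals conserve the number of observed positions", {
  m <- fixtureModel
  # brute-force recount of positions occupying each (family, slot)
  recount <- function(famName) {
    tp <- m@templates[[famName]]
    K <- length(tp@slots)
    tot <- integer(K)
    for (i in seq_len(nrow(fixtureCorpus))) {
      r <- rle(strsplit(fixtureCorpus$structure[[i]], "")[[1]])
      for (b in seq_along(r$values)) {
        ty <- r$values[[b]]; len <- r$lengths[[b]]
        fams <- if (ty == "H") c("H_fwd", "H_bwd")
                else if (ty == "T") {
                  if (len <= 3) "T3" else if (len == 4) "T4" else "T5"
                } else ty
        if (!famName %in% fams) next
        for (pos in seq_len(len)) {
          k <- if (tp@direction == "backward") min(len - pos + 1L, K)
               else min(pos, K)
          tot[[k]] <- tot[[k]] + 1L
        }
      }
    }
    tot
  }
  for (fam in c("H_fwd", "H_bwd", "E", "C", "T3", "T5")) {
    expected <- recount(fam)
    for (k in seq_along(m@tables[[fam]])) {
      slot <- m@tables[[fam]][[k]]
      expect_identical(sum(slot$counts[["."]] %||% integer(20)),
                       expected[[k]])
      # conditioned slots: context-specific counts sum to the backoff
      if (length(slot$offsets)) {
        keys <- setdiff(ls(slot$counts, all.names = TRUE), ".")
        ctxSum <- sum(vapply(keys, function(k2) sum(slot$counts[[k2]]),
                             numeric(1)))
        expect_identical(as.integer(ctxSum), expected[[k]])
      }
    }
  }
})

test_that("smoothedProb implements the add-one posterior mean", {
  m0 <- emptyModel()
  # zero counts: exactly 1/20 for every amino acid
  for (aa in c("A", "K", "Y"))
    expect_identical(smoothedProb(m0@tables$E[[1]], character(), aa), 0.05)
  # counts {A: 4}: p(A) = 5/24
  tbl <- list(offsets = integer(),
              counts = local({
                e <- new.env(parent = emptyenv())
                v <- integer(20); v[1] <- 4L
                assign(".", v, envir = e)
                e
              }))
  expect_identical(smoothedProb(tbl, character(), "A"), 5 / 24)
  expect_identical(smoothedProb(tbl, character(), "C"), 1 / 24)
})

test_that("smoothed probabilities sum to one over the alphabet", {
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  m <- fixtureModel
  for (fam in c("H_fwd", "E", "C")) {
    slot <- m@tables[[fam]][[length(m@tables[[fam]])]]
    keys <- utils::head(ls(slot$counts, all.names = TRUE), 5)
    for (k in keys) {
      ctx <- if (k == ".") character() else strsplit(k, "")[[1]]
      s <- sum(vapply(aa, function(a) smoothedProb(slot, ctx, a),
                      numeric(1)))
      expect_equal(s, 1, tolerance = 1e-12)
    }
  }
})

test_that("an extra observation moves the smoothed estimate monotonically", {
  set.seed(4)
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  mkTable <- function(counts) {
    e <- new.env(parent = emptyenv())
    assign(".", as.integer(counts), envir = e)
    list(offsets = integer(), counts = e)
  }
  for (rep in 1:20) {
    v <- as.integer(rpois(20, 3))
    t1 <- mkTable(v)
    i <- sample.int(20, 1)
    v2 <- v; v2[i] <- v2[i] + 1L
    t2 <- mkTable(v2)
    expect_gt(smoothedProb(t2, character(), aa[i]),
              smoothedProb(t1, character(), aa[i]))
    for (j in sample(setdiff(1:20, i), 3))
      expect_lt(smoothedProb(t2, character(), aa[j]),
                smoothedProb(t1, character(), aa[j]))
  }
})

test_that("training rejects empty or fully invalid corpora", {
  expect_error(trainModel(data.frame(id = character(),
                                     sequence = character(),
                                     structure = character())), "empty")
  expect_warning(
    expect_error(trainModel(data.frame(id = "bad", sequence = "MKV",
                                       structure = "HHH")), "no valid"),
    "invalid")
})
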