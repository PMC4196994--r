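# Dependency templates: default conditioning sets, context resolution,
# and structural invariants.

test_that("default templates expose the documented conditioning sets", {
  tp <- defaultTemplates()
  expect_identical(names(tp), c("H_fwd", "H_bwd", "E", "C", "T3", "T4", "T5"))
  expect_identical(tp$H_fwd@slots,
                   list(integer(), -1L, c(-1L, -2L), c(-1L, -2L),
                        c(-1L, -3L, -4L)))
  # strand: six distinct slots before interior reuse
  expect_length(tp$E@slots, 6L)
  expect_identical(tp$E@slots[[5L]], c(-2L, -4L))
  expect_identical(tp$C@slots, list(integer(), -1L, c(-1L, -2L)))
  # turn length classes 3, 4, >= 5
  expect_length(tp$T3@slots, 3L)
  expect_length(tp$T4@slots, 4L)
  expect_length(tp$T5@slots, 5L)
})

test_that("forward and backward helix templates are exact mirror images", {
  tp <- defaultTemplates()
  expect_identical(lapply(tp$H_bwd@slots, function(o) -o), tp$H_fwd@slots)
  expect_identical(tp$H_bwd@direction, "backward")
})

test_that("context table sizes match the conditioning arity", {
  tp <- defaultTemplates()
  # slot 3 of the forward helix conditions on two residues: 400 contexts
  expect_equal(20^length(tp$H_fwd@slots[[3L]]), 400)
  # the interior helix slot conditions on three residues: 8,000 contexts
  expect_equal(20^length(tp$H_fwd@slots[[5L]]), 8000)
})

test_that("conditioning offsets resolve inside the block for lengths 1..30", {
  tp <- defaultTemplates()
  res30 <- paste(rep("A", 30), collapse = "")
  for (fam in names(tp)) {
    for (len in 1:30) {
      r <- substr(res30, 1, len)
      for (pos in seq_len(len))
        expect_no_error(contextKey(tp[[fam]], len, pos, r))
    }
  }
})

test_that("contextKey applies template offsets in declared order", {
  tp <- defaultTemplates()
  # helix interior slot at position 5 of MKVLA: offsets (-1, -3, -4)
  expect_identical(contextKey(tp$H_fwd, 5, 5, "MKVLA"), c("L", "K", "M"))
  # strand slot 3 conditions two back
  expect_identical(contextKey(tp$E, 3, 3, "ACD"), "A")
  # slot 1 of any family is unconditional
  expect_identical(contextKey(tp$C, 4, 1, "ACDE"), character())
  # short helix truncates: position 3 of a length-3 block uses slot 3
  expect_identical(contextKey(tp$H_fwd, 3, 3, "MKV"), c("K", "M"))
  # backward helix anchors at the C-terminus: position 4 of 5 is slot 2
  expect_identical(contextKey(tp$H_bwd, 5, 4, "MKVLA"), "A")
})

test_that("templates survive a YAML round trip", {
  tp <- defaultTemplates()
  path <- withr::local_tempfile(fileext = ".yaml")
  templatesToYaml(tp, path)
  tp2 <- templatesFromYaml(path)
  expect_identical(names(tp2), names(tp))
  for (fam in names(tp)) {
    expect_identical(tp2[[fam]]@type, tp[[fam]]@type)
    expect_identical(tp2[[fam]]@direction, tp[[fam]]@direction)
    expect_identical(tp2[[fam]]@slots, tp[[fam]]@slots)
  }
})

test_that("template validity rejects offsets escaping the block", {
  expect_error(DependencyTemplate("H", "forward", list(-1L)), "escape")
  expect_error(DependencyTemplate("H", "forward", list(integer(), 1L)),
               "negative")
  expect_error(DependencyTemplate("H", "backward", list(integer(), 2L)),
               "escape")
})
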