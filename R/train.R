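# Estimation of the position-specific conditional amino-acid
# distributions by Dirichlet-multinomial posterior means: each observed
# (type, slot, context, residue) increments a count table, and the
# smoothed probability of amino acid a given context c is
# (n_a(c) + alpha) / (n(c) + 20 alpha).

.newSlotTable <- function(offsets) {
  list(offsets = as.integer(offsets),
       counts = new.env(hash = TRUE, parent = emptyenv()))
}

# Every slot keeps an unconditional count vector under key ""; slots
# with conditioning additionally key specific contexts. Contexts that
# contain the unknown residue code fall back to "" at both training and
# evaluation time.
.bumpCount <- function(env, key, resIdx) {
  v <- env[[key]]
  if (is.null(v)) v <- integer(20L)
  v[resIdx] <- v[resIdx] + 1L
  assign(key, v, envir = env)
}

.emptyTables <- function(templates) {
  lapply(templates, function(tp) lapply(tp@slots, .newSlotTable))
}

# Count one block's residues (integer codes) into a family's tables.
.countBlock <- function(family, template, codes) {
  len <- length(codes)
  K <- length(template@slots)
  backward <- template@direction == "backward"
  for (pos in seq_len(len)) {
    res <- codes[[pos]]
    if (res == 21L) next  # unknown residues are never counted
    k <- if (backward) min(len - pos + 1L, K) else min(pos, K)
    slot <- family[[k]]
    off <- slot$offsets
    if (length(off)) {
      ctx <- codes[pos + off]
      if (any(ctx == 21L)) {
        .bumpCount(slot$counts, .NOCTX, res)  # back off: unknown in context
      } else {
        .bumpCount(slot$counts, paste(.AA20[ctx], collapse = ""), res)
        .bumpCount(slot$counts, .NOCTX, res)
      }
    } else {
      .bumpCount(slot$counts, .NOCTX, res)
    }
  }
}

#' Train a block-likelihood model from a labeled corpus
#'
#' Walks every block of every record and increments the count table for
#' its (type, slot, conditioning context). Helix blocks are counted
#' under both the forward and the mirrored backward template; turn
#' blocks under the table set of their length class (3, 4, or >= 5).
#' Short blocks populate only the slots they reach. Records whose
#' structure string fails the constraint set are skipped with a warning.
#'
#' @param corpus data frame with columns `id`, `sequence`, `structure`
#'   (as returned by [readPaired()] or [simulateCorpus()]).
#' @param templates dependency templates (default [defaultTemplates()]).
#' @param constraints the [ConstraintSet-class] records must satisfy.
#' @param alpha Dirichlet smoothing hyperparameter per amino acid.
#' @param mixtureWeight helix forward-component weight `w`; the helix
#'   block likelihood is `w * forward + (1 - w) * backward`.
#' @return A [SecStructModel-class].
#' @examples
#' m <- trainModel(data.frame(id = "a", sequence = "MKVLA",
#'                            structure = "CHHHC"))
#' smoothedProb(m@tables$H_fwd[[1]], character(), "K")  # (1+1)/(1+20)
#' @export
trainModel <- function(corpus, templates = defaultTemplates(),
                       constraints = defaultConstraints(), alpha = 1,
                       mixtureWeight = 0.5) {
  if (is.null(corpus) || nrow(as.data.frame(corpus)) == 0L)
    .stopf("training corpus is empty")
  corpus <- as.data.frame(corpus)
  stopifnot(all(c("id", "sequence", "structure") %in% names(corpus)))
  tables <- .emptyTables(templates)
  blockCounts <- c(H = 0L, E = 0L, T = 0L, C = 0L)
  nSkipped <- 0L
  for (i in seq_len(nrow(corpus))) {
    seqStr <- corpus$sequence[[i]]
    ssStr <- corpus$structure[[i]]
    if (nchar(seqStr) != nchar(ssStr)) {
      warning("record ", corpus$id[[i]], ": sequence/structure length mismatch; skipped")
      nSkipped <- nSkipped + 1L
      next
    }
    ann <- tryCatch(linearToBlocks(ssStr), error = function(e) NULL)
    if (is.null(ann) || !isTRUE(c(validateAnnotation(ann, constraints)))) {
      warning("record ", corpus$id[[i]], ": invalid structure under constraints; skipped")
      nSkipped <- nSkipped + 1L
      next
    }
    codes <- .aaCodes(seqStr)
    ends <- cumsum(ann@lengths)
    starts <- ends - ann@lengths + 1L
    for (b in seq_along(ann@types)) {
      ty <- ann@types[[b]]
      bc <- codes[starts[[b]]:ends[[b]]]
      blockCounts[[ty]] <- blockCounts[[ty]] + 1L
      for (fam in .familyFor(ty, ann@lengths[[b]]))
        .countBlock(tables[[fam]], templates[[fam]], bc)
    }
  }
  if (sum(blockCounts) == 0L)
    .stopf("no valid training records")
  new("SecStructModel", tables = tables, templates = templates,
      constraints = constraints, alpha = alpha,
      mixtureWeight = mixtureWeight,
      meta = list(blockCounts = blockCounts, nRecords = nrow(corpus),
                  nSkipped = nSkipped, formatVersion = 1L))
}

#' An untrained model (all counts zero)
#'
#' Every emission distribution is the uniform 1/20, which makes the
#' likelihood flat; useful for tests and as a sampling-model-free
#' baseline.
#'
#' @inheritParams trainModel
#' @return A [SecStructModel-class] with empty count tables.
#' @export
emptyModel <- function(templates = defaultTemplates(),
                       constraints = defaultConstraints(), alpha = 1,
                       mixtureWeight = 0.5) {
  new("SecStructModel", tables = .emptyTables(templates),
      templates = templates, constraints = constraints, alpha = alpha,
      mixtureWeight = mixtureWeight,
      meta = list(blockCounts = c(H = 0L, E = 0L, T = 0L, C = 0L),
                  nRecords = 0L, nSkipped = 0L, formatVersion = 1L))
}

#' Dirichlet-multinomial smoothed emission probability
#'
#' Returns `(count(aa | context) + alpha) / (n(context) + 20 alpha)`.
#' An unseen context has all-zero counts, giving exactly `1/20` at
#' `alpha = 1`.
#'
#' @param table a slot table (element of a model's family list), with
#'   fields `offsets` and `counts`.
#' @param context conditioning residues (character vector or collapsed
#'   string; empty for unconditional slots).
#' @param aminoAcid one-letter code of the emitted residue.
#' @param alpha Dirichlet hyperparameter.
#' @return The smoothed probability.
#' @export
smoothedProb <- function(table, context, aminoAcid, alpha = 1) {
  stopifnot(alpha > 0)
  key <- paste(context, collapse = "")
  if (!nzchar(key)) key <- .NOCTX
  v <- table$counts[[key]]
  if (is.null(v)) v <- integer(20L)
  (v[[.aaIndex(aminoAcid)]] + alpha) / (sum(v) + 20 * alpha)
}

# Full smoothed 20-vector for a context key (internal, hot path).
.slotProbVec <- function(slot, key, alpha) {
  v <- slot$counts[[key]]
  if (is.null(v)) return(rep.int(1 / 20, 20L))
  (v + alpha) / (sum(v) + 20 * alpha)
}

#' Canonical list form of a model
#'
#' Converts the environment-backed count tables to nested lists with
#' sorted context keys. Two models are equal iff their canonical forms
#' are; this is the representation serialized by [writeModel()].
#'
#' @param model a [SecStructModel-class].
#' @return A named list.
#' @export
modelAsList <- function(model) {
  tables <- lapply(model@tables, function(family)
    lapply(family, function(slot) {
      keys <- sort(ls(slot$counts, all.names = TRUE))
      cnt <- lapply(keys, function(k) slot$counts[[k]])
      names(cnt) <- keys
      list(offsets = slot$offsets, counts = cnt)
    }))
  list(format = "BlockSS-model", version = model@meta$formatVersion,
       alpha = model@alpha, mixtureWeight = model@mixtureWeight,
       templates = lapply(model@templates, function(tp)
         list(type = tp@type, direction = tp@direction, slots = tp@slots)),
       constraints = list(
         minLengths = model@constraints@minLengths,
         forbiddenAdjacency = model@constraints@forbiddenAdjacency,
         terminalType = model@constraints@terminalType),
       meta = model@meta, tables = tables)
}

# Rebuild a model from its canonical list form.
.modelFromList <- function(x) {
  tables <- lapply(x$tables, function(family)
    lapply(family, function(slot) {
      env <- new.env(hash = TRUE, parent = emptyenv())
      for (k in names(slot$counts)) assign(k, slot$counts[[k]], envir = env)
      list(offsets = as.integer(slot$offsets), counts = env)
    }))
  templates <- lapply(x$templates, function(tp)
    DependencyTemplate(tp$type, tp$direction, tp$slots))
  constraints <- ConstraintSet(
    minLengths = x$constraints$minLengths,
    forbiddenAdjacency = x$constraints$forbiddenAdjacency,
    terminalType = x$constraints$terminalType)
  new("SecStructModel", tables = tables, templates = templates,
      constraints = constraints, alpha = x$alpha,
      mixtureWeight = x$mixtureWeight, meta = x$meta)
}

#' @param target,current models to compare.
#' @param ... passed to [base::all.equal()].
#' @rdname SecStructModel-class
#' @exportS3Method base::all.equal
all.equal.SecStructModel <- function(target, current, ...) {
  all.equal(modelAsList(target), modelAsList(current), ...)
}
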