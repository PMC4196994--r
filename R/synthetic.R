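# Synthetic corpus generator: block structures drawn under the hard
# structural constraints with amino acids emitted from known
# position-specific tables under the dependency templates. Used for
# fixtures, parameter-recovery experiments and end-to-end tests.

#' Construct a generator specification
#'
#' Structured blocks (H, E, T) are separated by coil spacers; all
#' generated annotations satisfy the constraint set by construction.
#' Block lengths are the type minimum plus a geometric tail with the
#' stated mean. One emission table per (family, slot) is drawn at
#' construction from a symmetric Dirichlet with shape `concentration`
#' (smaller = more skewed amino-acid preferences), using `seed`;
#' context-specific overrides may be supplied via `contextTables`.
#'
#' @param seed integer seed for drawing the emission tables.
#' @param typeWeights sampling weights of structured block types.
#' @param lengthMeans named mean extra length beyond the minimum for
#'   `H, E, T, C`.
#' @param concentration Dirichlet shape for emission tables.
#' @param templates dependency templates used for emission.
#' @param constraints a [ConstraintSet-class].
#' @param helixMixture probability a helix block is emitted under the
#'   backward template (default 0: forward only).
#' @param emissions optional explicit named list (family -> list of
#'   per-slot 20-probability vectors); drawn when `NULL`.
#' @return A [GeneratorSpec-class].
#' @export
generatorSpec <- function(seed = 1L,
                          typeWeights = c(H = 0.4, E = 0.3, T = 0.3),
                          lengthMeans = c(H = 6, E = 2.5, T = 1, C = 2),
                          concentration = 2,
                          templates = defaultTemplates(),
                          constraints = defaultConstraints(),
                          helixMixture = 0,
                          emissions = NULL) {
  stopifnot(all(c("H", "E", "T") %in% names(typeWeights)),
            all(.STATES %in% names(lengthMeans)), concentration > 0)
  if (is.null(emissions)) {
    emissions <- local({
      rs <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
      set.seed(seed)
      out <- lapply(templates, function(tp)
        lapply(tp@slots, function(off) {
          p <- stats::rgamma(20L, shape = concentration)
          stats::setNames(p / sum(p), .AA20)
        }))
      if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv())
      out
    })
  }
  new("GeneratorSpec", typeWeights = typeWeights[c("H", "E", "T")],
      lengthMeans = lengthMeans[.STATES], concentration = concentration,
      emissions = emissions, templates = templates,
      constraints = constraints, helixMixture = helixMixture,
      seed = as.integer(seed))
}

#' @rdname GeneratorSpec-class
#' @param object a `GeneratorSpec`.
#' @export
setMethod("show", "GeneratorSpec", function(object) {
  cat(sprintf(paste0("GeneratorSpec: weights H:%.2f E:%.2f T:%.2f, ",
                     "concentration %.2f, seed %d\n"),
              object@typeWeights[["H"]], object@typeWeights[["E"]],
              object@typeWeights[["T"]], object@concentration, object@seed))
})

# geometric tail with the given mean
.rgeomMean <- function(mean) {
  if (mean <= 0) return(0L)
  stats::rgeom(1L, prob = 1 / (1 + mean))
}

#' Sample a valid block structure
#'
#' Coil spacers alternate with structured blocks; the structure always
#' starts and ends in coil, never places helix next to strand, and
#' respects every minimum length, so the result passes
#' [validateAnnotation()] by construction. When `L` is too short for
#' any structured block the all-coil annotation is returned.
#'
#' @param spec a [GeneratorSpec-class].
#' @param L total length.
#' @return A [BlockAnnotation-class] of total length `L`.
#' @export
sampleStructure <- function(spec, L) {
  stopifnot(L >= 1L)
  minLen <- spec@constraints@minLengths
  minStruct <- min(minLen[c("H", "E", "T")])
  types <- character()
  lens <- integer()
  remaining <- L
  repeat {
    # coil spacer (possibly closing the chain)
    lc <- 1L + .rgeomMean(spec@lengthMeans[["C"]])
    if (remaining - lc < minStruct + 1L) lc <- remaining
    types <- c(types, "C")
    lens <- c(lens, min(lc, remaining))
    remaining <- remaining - min(lc, remaining)
    if (remaining == 0L) break
    # structured block, leaving room for a closing coil
    feasible <- names(spec@typeWeights)[minLen[names(spec@typeWeights)] + 1L <= remaining]
    ty <- feasible[sample.int(length(feasible), 1L,
                              prob = spec@typeWeights[feasible])]
    lb <- min(minLen[[ty]] + .rgeomMean(spec@lengthMeans[[ty]]),
              remaining - 1L)
    types <- c(types, ty)
    lens <- c(lens, lb)
    remaining <- remaining - lb
  }
  BlockAnnotation(types, lens)
}

# emit one block's residues (integer codes) under a family's tables
.emitBlock <- function(spec, fam, len) {
  template <- spec@templates[[fam]]
  tables <- spec@emissions[[fam]]
  K <- length(template@slots)
  backward <- template@direction == "backward"
  codes <- integer(len)
  order <- if (backward) len:1 else seq_len(len)
  for (pos in order) {
    k <- if (backward) min(len - pos + 1L, K) else min(pos, K)
    p <- tables[[k]]
    codes[[pos]] <- sample.int(20L, 1L, prob = p)
  }
  codes
}

#' Emit a sequence for a block annotation
#'
#' Residues are drawn slot-by-slot from the spec's emission tables
#' under the dependency templates (helix blocks are emitted under the
#' backward template with probability `helixMixture`).
#'
#' @param spec a [GeneratorSpec-class].
#' @param annotation a valid [BlockAnnotation-class].
#' @return The amino-acid sequence (string).
#' @export
sampleSequence <- function(spec, annotation) {
  stopifnot(is(annotation, "BlockAnnotation"))
  out <- integer(0)
  for (b in seq_along(annotation@types)) {
    ty <- annotation@types[[b]]
    len <- annotation@lengths[[b]]
    fams <- .familyFor(ty, len)
    fam <- if (length(fams) == 2L) {
      if (stats::runif(1) < spec@helixMixture) fams[[2L]] else fams[[1L]]
    } else fams
    out <- c(out, .emitBlock(spec, fam, len))
  }
  paste(.AA20[out], collapse = "")
}

#' Simulate a labeled corpus
#'
#' @param spec a [GeneratorSpec-class].
#' @param n number of records.
#' @param lengthRange range from which chain lengths are drawn
#'   uniformly.
#' @param idPrefix record id prefix.
#' @return Data frame with columns `id`, `sequence`, `structure`.
#' @export
simulateCorpus <- function(spec, n, lengthRange = c(30L, 60L),
                           idPrefix = "syn") {
  stopifnot(n >= 1L)
  ids <- sprintf("%s%04d", idPrefix, seq_len(n))
  Ls <- sample.int(lengthRange[[2L]] - lengthRange[[1L]] + 1L, n,
                   replace = TRUE) + lengthRange[[1L]] - 1L
  seqs <- character(n)
  sss <- character(n)
  for (i in seq_len(n)) {
    ann <- sampleStructure(spec, Ls[[i]])
    seqs[[i]] <- sampleSequence(spec, ann)
    sss[[i]] <- blocksToLinear(ann)
  }
  data.frame(id = ids, sequence = seqs, structure = sss,
             stringsAsFactors = FALSE)
}

#' Simulate a noisy MSA profile around a true structure
#'
#' Stands in for alignment-derived evidence: at each position, `depth`
#' pseudo-homologs report the true state with probability
#' `1 - errorRate`, otherwise a uniformly chosen other state.
#'
#' @param truth true linear 4-state string.
#' @param depth number of draws per position (0 gives the zero matrix,
#'   i.e. a NonInfo fallback downstream).
#' @param errorRate per-draw error probability in `[0, 1]`.
#' @param alpha Dirichlet hyperparameters for the resulting profile.
#' @return An [MsaProfile-class].
#' @export
corruptMsaProfile <- function(truth, depth, errorRate, alpha = 1) {
  stopifnot(errorRate >= 0, errorRate <= 1, depth >= 0)
  L <- nchar(truth)
  tru <- .stateIndex(strsplit(truth, "")[[1]])
  counts <- matrix(0L, L, 4L, dimnames = list(NULL, .STATES))
  if (depth > 0) {
    for (l in seq_len(L)) {
      p <- rep(errorRate / 3, 4L)
      p[[tru[[l]]]] <- 1 - errorRate
      counts[l, ] <- as.integer(stats::rmultinom(1L, depth, p))
    }
  }
  MsaProfile(counts, alpha = alpha)
}
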