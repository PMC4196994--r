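#' @import methods
NULL

#' Block parameterization of a secondary structure
#'
#' An ordered list of (type, length) segments encoding a protein's
#' secondary structure. Types are the four states `H` (helix), `E`
#' (strand), `T` (turn) and `C` (coil); lengths are positive and sum to
#' the protein length `L`. The block list is equivalent to the linear
#' per-residue state string (see [blocksToLinear()] and
#' [linearToBlocks()]), except that a block list may contain adjacent
#' blocks of the same type; [canonicalizeAnnotation()] merges them.
#'
#' @slot types character vector of block types, one of `"H","E","T","C"`.
#' @slot lengths integer vector of block lengths, same length as `types`.
#' @export
setClass("BlockAnnotation",
         representation(types = "character", lengths = "integer"))

setValidity("BlockAnnotation", function(object) {
  msg <- character()
  if (length(object@types) != length(object@lengths))
    msg <- c(msg, "types and lengths must have equal length")
  if (length(object@types) < 1L)
    msg <- c(msg, "an annotation must contain at least one block")
  if (!all(object@types %in% .STATES))
    msg <- c(msg, "block types must be in {H, E, T, C}")
  if (length(object@lengths) && (anyNA(object@lengths) || any(object@lengths < 1L)))
    msg <- c(msg, "block lengths must be positive integers")
  if (length(msg)) msg else TRUE
})

#' Construct a BlockAnnotation
#'
#' @param types character vector of block types over `{H,E,T,C}`.
#' @param lengths positive integer vector of block lengths.
#' @return A [BlockAnnotation-class] object.
#' @examples
#' BlockAnnotation(c("C", "H", "C"), c(1, 3, 1))
#' @export
BlockAnnotation <- function(types, lengths) {
  new("BlockAnnotation", types = as.character(types),
      lengths = as.integer(lengths))
}

#' Hard structural constraints on block annotations
#'
#' Encodes the validity rules for an annotation: per-type minimum block
#' lengths, forbidden ordered adjacencies between block types, and a
#' required terminal type for the first and last block. The defaults are
#' the standard rules: helix, strand and turn blocks span at least 3
#' residues, coil at least 1; helix may not abut strand in either order;
#' and a protein starts and ends in coil.
#'
#' Constraints are plain data so that tests and experiments can relax
#' them (e.g. to build tiny exhaustive state spaces).
#'
#' @slot minLengths named integer vector with names `H,E,T,C`.
#' @slot forbiddenAdjacency two-column character matrix of forbidden
#'   ordered (left, right) type pairs.
#' @slot terminalType required type of first and last block (`NA` for
#'   no requirement).
#' @export
setClass("ConstraintSet",
         representation(minLengths = "integer",
                        forbiddenAdjacency = "matrix",
                        terminalType = "character"))

setValidity("ConstraintSet", function(object) {
  msg <- character()
  if (!identical(sort(names(object@minLengths)), sort(.STATES)))
    msg <- c(msg, "minLengths must be named with H, E, T, C")
  if (any(object@minLengths < 1L))
    msg <- c(msg, "minimum lengths must be >= 1")
  fa <- object@forbiddenAdjacency
  if (ncol(fa) != 2L || (length(fa) && !all(fa %in% .STATES)))
    msg <- c(msg, "forbiddenAdjacency must be a 2-column matrix of states")
  if (length(object@terminalType) != 1L ||
      (!is.na(object@terminalType) && !object@terminalType %in% .STATES))
    msg <- c(msg, "terminalType must be a single state or NA")
  if (length(msg)) msg else TRUE
})

#' @param minLengths named vector of per-type minimum block lengths.
#' @param forbiddenAdjacency two-column character matrix of forbidden
#'   ordered type pairs.
#' @param terminalType required first/last block type, or `NA`.
#' @return A [ConstraintSet-class].
#' @rdname ConstraintSet-class
#' @examples
#' defaultConstraints()
#' @export
ConstraintSet <- function(minLengths = c(H = 3L, E = 3L, T = 3L, C = 1L),
                          forbiddenAdjacency = rbind(c("H", "E"), c("E", "H")),
                          terminalType = "C") {
  ml <- as.integer(minLengths)
  names(ml) <- names(minLengths)
  fa <- forbiddenAdjacency
  if (is.null(fa)) fa <- matrix(character(), ncol = 2L)
  new("ConstraintSet", minLengths = ml[.STATES],
      forbiddenAdjacency = fa, terminalType = as.character(terminalType))
}

#' @return The default constraint set.
#' @rdname ConstraintSet-class
#' @export
defaultConstraints <- function() ConstraintSet()

#' Dependency template for one block type
#'
#' Declares, for each position slot within a block, the relative offsets
#' of the residues its emission distribution conditions on. Positions
#' beyond the last explicit slot reuse the last ("interior") slot. For
#' forward templates slot k sits at the k-th residue of the block and
#' offsets are negative; for backward templates slot k sits at the k-th
#' residue counted from the C-terminus and offsets are positive.
#'
#' @slot type block type the template applies to.
#' @slot direction `"forward"` or `"backward"`.
#' @slot slots list of integer offset vectors; `slots[[k]]` conditions
#'   slot k (possibly empty).
#' @export
setClass("DependencyTemplate",
         representation(type = "character", direction = "character",
                        slots = "list"))

setValidity("DependencyTemplate", function(object) {
  msg <- character()
  if (!object@type %in% .STATES) msg <- c(msg, "type must be a state")
  if (!object@direction %in% c("forward", "backward"))
    msg <- c(msg, "direction must be forward or backward")
  if (!length(object@slots)) msg <- c(msg, "slot list must be non-empty")
  for (k in seq_along(object@slots)) {
    off <- object@slots[[k]]
    if (!length(off)) next
    if (object@direction == "forward") {
      if (any(off >= 0L)) msg <- c(msg, "forward offsets must be negative")
      if (any(k + off < 1L))
        msg <- c(msg, sprintf("slot %d offsets escape the block", k))
    } else {
      if (any(off <= 0L)) msg <- c(msg, "backward offsets must be positive")
      if (any(off > k - 1L))
        msg <- c(msg, sprintf("slot %d offsets escape the block", k))
    }
  }
  if (length(msg)) msg else TRUE
})

#' @param type block type.
#' @param direction `"forward"` or `"backward"`.
#' @param slots list of integer offset vectors.
#' @return A [DependencyTemplate-class].
#' @rdname DependencyTemplate-class
#' @export
DependencyTemplate <- function(type, direction, slots) {
  new("DependencyTemplate", type = type, direction = direction,
      slots = lapply(slots, as.integer))
}

#' A trained block-likelihood model
#'
#' Holds the complete set of position-specific conditional amino-acid
#' count tables (helix forward and backward, strand, coil, and turn by
#' length class), the dependency templates and constraint set used at
#' training time, the Dirichlet smoothing hyperparameter, and the helix
#' forward/backward mixture weight.
#'
#' Count tables are environments keyed by conditioning context for O(1)
#' lookup; use [modelAsList()] for a canonical, comparable form.
#'
#' @slot tables named list of table families; each family is a list of
#'   slot tables with fields `offsets`, `counts` (environment mapping
#'   context key to an integer 20-vector) and `backoff` (unconditional
#'   integer 20-vector for the slot).
#' @slot templates named list of [DependencyTemplate-class] objects.
#' @slot constraints the [ConstraintSet-class] used at training.
#' @slot alpha Dirichlet hyperparameter per amino acid (default 1).
#' @slot mixtureWeight helix forward-component weight in `[0, 1]`.
#' @slot meta list of training metadata (block counts per type, corpus
#'   size, format version).
#' @export
setClass("SecStructModel",
         representation(tables = "list", templates = "list",
                        constraints = "ConstraintSet", alpha = "numeric",
                        mixtureWeight = "numeric", meta = "list"))

setValidity("SecStructModel", function(object) {
  msg <- character()
  if (object@alpha <= 0) msg <- c(msg, "alpha must be > 0")
  if (object@mixtureWeight < 0 || object@mixtureWeight > 1)
    msg <- c(msg, "mixtureWeight must be in [0, 1]")
  need <- c("H_fwd", "H_bwd", "E", "C", "T3", "T4", "T5")
  if (!all(need %in% names(object@tables)))
    msg <- c(msg, "tables must contain H_fwd, H_bwd, E, C, T3, T4, T5")
  if (length(msg)) msg else TRUE
})

#' Per-position secondary-structure evidence from aligned homologs
#'
#' Counts of the four states observed at each query position among
#' aligned structures of known secondary structure, together with the
#' per-position effective depth (alignment depth minus gaps) and the
#' Dirichlet hyperparameters. The posterior-mean matrix `q` with rows
#' `(m_j + alpha) / (n_j + sum(alpha))` is the position-wise prior used
#' by [logPriorMsa()].
#'
#' @slot counts L x 4 integer matrix (columns `H,E,T,C`).
#' @slot depth integer vector of per-position effective depths `n_j`.
#' @slot alpha Dirichlet hyperparameters, one per state (default all 1).
#' @slot q L x 4 posterior-mean matrix; rows sum to 1.
#' @export
setClass("MsaProfile",
         representation(counts = "matrix", depth = "integer",
                        alpha = "numeric", q = "matrix"))

setValidity("MsaProfile", function(object) {
  msg <- character()
  if (ncol(object@counts) != 4L || ncol(object@q) != 4L)
    msg <- c(msg, "counts and q must have 4 columns")
  if (nrow(object@counts) != length(object@depth))
    msg <- c(msg, "depth length must equal number of positions")
  if (length(object@alpha) != 4L || any(object@alpha <= 0))
    msg <- c(msg, "alpha must be 4 positive values")
  rs <- rowSums(object@counts)
  if (length(rs) && any(abs(rs - object@depth) > 0))
    msg <- c(msg, "depth must equal the row sums of counts")
  if (nrow(object@q) && any(abs(rowSums(object@q) - 1) > 1e-12))
    msg <- c(msg, "rows of q must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Construct an MsaProfile from per-position state counts
#'
#' @param counts L x 4 non-negative integer matrix with columns in the
#'   order `H, E, T, C` (column names, if present, are honored).
#' @param alpha Dirichlet hyperparameters (length 4 or scalar).
#' @return An [MsaProfile-class].
#' @examples
#' m <- matrix(c(3, 0, 0, 1), nrow = 1)
#' msaPositionProbs(MsaProfile(m), 1)  # (3+1)/8, 1/8, 1/8, (1+1)/8
#' @export
MsaProfile <- function(counts, alpha = 1) {
  counts <- as.matrix(counts)
  if (!is.null(colnames(counts))) {
    if (!all(.STATES %in% colnames(counts)))
      .stopf("count matrix columns must include H, E, T, C")
    counts <- counts[, .STATES, drop = FALSE]
  } else if (ncol(counts) != 4L) {
    .stopf("count matrix must have 4 columns (H, E, T, C)")
  }
  if (any(counts < 0)) .stopf("MSA counts must be non-negative")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(NULL, .STATES)
  alpha <- rep_len(as.numeric(alpha), 4L)
  depth <- as.integer(rowSums(counts))
  q <- (counts + matrix(alpha, nrow(counts), 4L, byrow = TRUE)) /
    (depth + sum(alpha))
  colnames(q) <- .STATES
  new("MsaProfile", counts = counts, depth = depth, alpha = alpha, q = q)
}

#' Posterior summary of a sampler run
#'
#' @slot marginals L x 4 matrix of per-position posterior state
#'   probabilities (columns `H,E,T,C`; rows sum to 1).
#' @slot map list with the best retained sample: `annotation`
#'   ([BlockAnnotation-class]), `logPost`, `iteration`.
#' @slot trace numeric vector of post-burnin log posterior values
#'   (thinned).
#' @slot blockCounts list with `total` (named probability vector over
#'   the canonical number of blocks M) and `byType` (list of four such
#'   vectors).
#' @slot stateFreq named numeric vector of visited-state frequencies
#'   (block-list keys), populated when `trackStates = TRUE`.
#' @slot diagnostics list: acceptance rate, validity rate, resampled
#'   move-kind count, seed, iteration counts.
#' @slot samples list of thinned retained [BlockAnnotation-class]
#'   samples (empty unless requested).
#' @export
setClass("PosteriorSummary",
         representation(marginals = "matrix", map = "list",
                        trace = "numeric", blockCounts = "list",
                        stateFreq = "numeric", diagnostics = "list",
                        samples = "list"))

#' Specification of the synthetic corpus generator
#'
#' Defines how synthetic (sequence, structure) pairs are produced:
#' structured-block type weights, per-type length distributions
#' (minimum plus a geometric tail), coil spacer lengths, and one
#' emission table per (type, slot) drawn once from a symmetric Dirichlet
#' with the stated concentration. Generated structures always satisfy
#' the constraint set by construction; sequences are emitted slot-by-slot
#' under the dependency templates.
#'
#' @slot typeWeights named weights for structured types `H, E, T`.
#' @slot lengthMeans named mean *extra* length beyond the minimum for
#'   `H, E, T, C` (geometric tails).
#' @slot concentration Dirichlet shape for drawing emission tables;
#'   smaller is more skewed.
#' @slot emissions named list (family -> list of per-slot 20-probability
#'   vectors) as drawn at construction.
#' @slot templates dependency templates used for emission.
#' @slot constraints the [ConstraintSet-class] generation respects.
#' @slot helixMixture probability a helix block is emitted under the
#'   backward template (default 0: forward only).
#' @slot seed integer seed used to draw the emission tables.
#' @export
setClass("GeneratorSpec",
         representation(typeWeights = "numeric", lengthMeans = "numeric",
                        concentration = "numeric", emissions = "list",
                        templates = "list", constraints = "ConstraintSet",
                        helixMixture = "numeric", seed = "integer"))

#' Confusion matrix with recall and precision normalizations
#'
#' Counts are predicted (rows) by actual (columns). The recall matrix
#' normalizes each column to 100; the precision matrix normalizes each
#' row to 100. Empty classes render as all-zero rows/columns and are
#' flagged.
#'
#' @slot counts K x K count matrix, rows = predicted, columns = actual.
#' @slot recall column-normalized percentages (columns sum to 100).
#' @slot precision row-normalized percentages (rows sum to 100).
#' @slot emptyActual,emptyPredicted character vectors of classes with no
#'   instances.
#' @export
setClass("ConfusionSummary",
         representation(counts = "matrix", recall = "matrix",
                        precision = "matrix", emptyActual = "character",
                        emptyPredicted = "character"))
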