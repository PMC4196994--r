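# Exact inference by exhaustive enumeration of valid block annotations,
# feasible for small L. This is the ground truth against which the
# Metropolis chain, the priors and the estimators are validated.

# Canonical key for a block list, e.g. "C1H3C1".
.annotationKey <- function(types, lengths)
  paste0(types, lengths, collapse = "")

#' Enumerate all valid block annotations of a given length
#'
#' Generates every block list of total length `L` that passes
#' [validateAnnotation()], each exactly once. By default two adjacent
#' blocks of the same type count as distinct states (each held to the
#' minimum length individually), mirroring the sampler's state space;
#' set `allowSameTypeAdjacency = FALSE` to enumerate only canonical
#' annotations.
#'
#' @param L total length (capped at `cap`; the space grows
#'   exponentially).
#' @param constraints a [ConstraintSet-class].
#' @param allowSameTypeAdjacency logical.
#' @param cap refuse enumeration beyond this length.
#' @return List of [BlockAnnotation-class] objects.
#' @examples
#' length(enumerateValid(5))  # 19
#' @export
enumerateValid <- function(L, constraints = defaultConstraints(),
                           allowSameTypeAdjacency = TRUE, cap = 14L) {
  stopifnot(L >= 1L)
  if (L > cap)
    .stopf("refusing to enumerate L = %d (cap %d): combinatorial explosion",
           L, cap)
  cc <- .constraintCodes(constraints)
  out <- vector("list", 0L)
  emit <- function(tyi, len)
    out[[length(out) + 1L]] <<- BlockAnnotation(.STATES[tyi], len)
  recurse <- function(remaining, tyi, len) {
    prev <- if (length(tyi)) tyi[[length(tyi)]] else NA_integer_
    for (t in 1:4) {
      if (!is.na(prev)) {
        if (cc$forbid[prev, t]) next
        if (!allowSameTypeAdjacency && prev == t) next
      } else if (!is.na(cc$termIdx) && t != cc$termIdx) next
      lmin <- cc$minLen[[t]]
      if (lmin > remaining) next
      for (l in lmin:remaining) {
        if (l == remaining) {
          if (is.na(cc$termIdx) || t == cc$termIdx)
            emit(c(tyi, t), c(len, l))
        } else {
          recurse(remaining - l, c(tyi, t), c(len, l))
        }
      }
    }
  }
  recurse(L, integer(), integer())
  out
}

#' Exact posterior over block annotations for small problems
#'
#' Enumerates the valid annotation space, scores every annotation under
#' the model likelihood and the chosen prior, and normalizes. Also
#' returns the exact per-position marginal state probabilities and the
#' exact (canonicalized) block-count distributions.
#'
#' @param model a [SecStructModel-class].
#' @param sequence amino-acid sequence (string), length within `cap`.
#' @param prior `"noninfo"` or `"msa"`.
#' @param profile an [MsaProfile-class] (required for the MSA prior).
#' @param constraints a [ConstraintSet-class].
#' @param cap maximum length for enumeration.
#' @return List with `annotations` (list), `keys`, `logPost`
#'   (unnormalized), `prob` (normalized; sums to 1), `marginals`
#'   (L x 4), `blockCounts` (list `total`, `byType` of named
#'   probability vectors).
#' @export
exactPosterior <- function(model, sequence, prior = c("noninfo", "msa"),
                           profile = NULL,
                           constraints = model@constraints, cap = 14L) {
  prior <- match.arg(prior)
  L <- nchar(sequence)
  anns <- enumerateValid(L, constraints, cap = cap)
  seg <- segmentLogLik(model, sequence)
  logq <- .priorPosMatrix(L, prior, profile)
  logPost <- vapply(anns, function(a) {
    ends <- cumsum(a@lengths)
    starts <- ends - a@lengths + 1L
    tyi <- .stateIndex(a@types)
    ll <- 0
    for (b in seq_along(ends))
      ll <- ll + seg[[a@types[[b]]]][starts[[b]], ends[[b]]]
    states <- rep(tyi, a@lengths)
    ll + sum(logq[cbind(seq_len(L), states)])
  }, numeric(1))
  if (all(!is.finite(logPost)))
    .stopf("degenerate input: every annotation has zero posterior mass")
  z <- .logSumExp(logPost)
  prob <- exp(logPost - z)
  marg <- matrix(0, L, 4L, dimnames = list(NULL, .STATES))
  Mtot <- numeric(0)
  byType <- list(H = numeric(0), E = numeric(0), T = numeric(0), C = numeric(0))
  addMass <- function(vec, key, p) {
    k <- as.character(key)
    if (is.na(match(k, names(vec)))) vec[k] <- p else vec[k] <- vec[k] + p
    vec
  }
  for (i in seq_along(anns)) {
    a <- anns[[i]]
    states <- rep(.stateIndex(a@types), a@lengths)
    marg[cbind(seq_len(L), states)] <-
      marg[cbind(seq_len(L), states)] + prob[[i]]
    can <- canonicalizeAnnotation(a)
    Mtot <- addMass(Mtot, nBlocks(can), prob[[i]])
    for (s in .STATES)
      byType[[s]] <- addMass(byType[[s]], sum(can@types == s), prob[[i]])
  }
  ord <- function(v) v[order(as.integer(names(v)))]
  list(annotations = anns,
       keys = vapply(anns, function(a) .annotationKey(a@types, a@lengths),
                     character(1)),
       logPost = logPost, prob = prob, marginals = marg,
       blockCounts = list(total = ord(Mtot), byType = lapply(byType, ord)))
}
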