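# Priors over block annotations: the constrained-uniform (NonInfo)
# prior and the MSA-informed prior built from per-position Dirichlet
# posterior means over the four states.

#' Constrained-uniform (NonInfo) log prior
#'
#' Equal weight on every annotation satisfying the hard structural
#' constraints: 0 for valid annotations, `-Inf` for invalid
#' (unnormalized).
#'
#' @param annotation a [BlockAnnotation-class].
#' @param constraints a [ConstraintSet-class].
#' @return 0 or `-Inf`.
#' @export
logPriorNonInfo <- function(annotation, constraints = defaultConstraints()) {
  if (isTRUE(c(validateAnnotation(annotation, constraints)))) 0 else -Inf
}

#' Posterior-mean state probabilities at one position
#'
#' Returns `(m_j + alpha) / (n_j + sum(alpha))` for position `j`; with
#' all-one hyperparameters and zero depth this is the uniform 1/4.
#'
#' @param profile an [MsaProfile-class].
#' @param j 1-based position.
#' @return Named numeric 4-vector (`H,E,T,C`) summing to 1.
#' @export
msaPositionProbs <- function(profile, j) {
  stopifnot(is(profile, "MsaProfile"))
  if (j < 1L || j > nrow(profile@q))
    .stopf("position %d out of range 1..%d", j, nrow(profile@q))
  profile@q[j, ]
}

#' MSA-informed log prior
#'
#' `-Inf` when the hard constraints are violated; otherwise the sum over
#' positions of the log posterior-mean probability of the annotation's
#' state at that position (a product of L position-wise p.m.f.'s, up to
#' the normalizing constant over valid annotations).
#'
#' @param annotation a [BlockAnnotation-class].
#' @param profile an [MsaProfile-class] of matching length.
#' @param constraints a [ConstraintSet-class].
#' @return Log prior up to a constant.
#' @export
logPriorMsa <- function(annotation, profile,
                        constraints = defaultConstraints()) {
  stopifnot(is(profile, "MsaProfile"))
  L <- sum(annotation@lengths)
  if (L != nrow(profile@q))
    .stopf("profile has %d positions but annotation covers %d",
           nrow(profile@q), L)
  if (!isTRUE(c(validateAnnotation(annotation, constraints)))) return(-Inf)
  states <- rep(.stateIndex(annotation@types), annotation@lengths)
  sum(log(profile@q[cbind(seq_len(L), states)]))
}

# L x 4 matrix of per-position log prior terms (zeros under NonInfo);
# the positional factor shared by the sampler and the oracle.
.priorPosMatrix <- function(L, prior = c("noninfo", "msa"), profile = NULL) {
  prior <- match.arg(prior)
  if (prior == "noninfo") {
    matrix(0, L, 4L, dimnames = list(NULL, .STATES))
  } else {
    if (is.null(profile)) .stopf("msa prior requires a profile")
    if (nrow(profile@q) != L)
      .stopf("profile length %d does not match sequence length %d",
             nrow(profile@q), L)
    log(profile@q)
  }
}

# Log prior of an integer-coded annotation given the positional matrix
# and constraint codes (internal; used by the R-level sampler path).
.logPriorFast <- function(tyi, len, logq, cc) {
  if (!.validFast(tyi, len, cc$minLen, cc$forbid, cc$termIdx)) return(-Inf)
  states <- rep(tyi, len)
  sum(logq[cbind(seq_along(states), states)])
}
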