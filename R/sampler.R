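# Metropolis sampler over block annotations with four proposal schemes
# (switch, boundary, split, merge) and exact Hastings correction. The
# R-level propose/accept functions expose single transitions for
# inspection and testing; runChain() drives the compiled chain.

#' A sampler chain state
#'
#' @slot annotation current [BlockAnnotation-class].
#' @slot logLik cached log-likelihood (`NA` until scored).
#' @slot logPrior cached log-prior (`NA` until scored).
#' @export
setClass("ChainState",
         representation(annotation = "BlockAnnotation", logLik = "numeric",
                        logPrior = "numeric"))

#' Initial chain state
#'
#' The all-coil single-block annotation, which is valid under any
#' constraint set requiring coil termini.
#'
#' @param L sequence length.
#' @param constraints a [ConstraintSet-class] (the initial state is
#'   checked against it).
#' @return A [ChainState-class] with unscored caches.
#' @export
initState <- function(L, constraints = defaultConstraints()) {
  stopifnot(L >= 1L)
  ann <- BlockAnnotation("C", L)
  if (!isTRUE(c(validateAnnotation(ann, constraints))))
    .stopf("the all-coil annotation is invalid under these constraints")
  new("ChainState", annotation = ann, logLik = NA_real_,
      logPrior = NA_real_)
}

#' Score a chain state's caches
#'
#' @param state a [ChainState-class].
#' @param model a [SecStructModel-class].
#' @param sequence amino-acid sequence.
#' @param prior `"noninfo"` or `"msa"`.
#' @param profile [MsaProfile-class] for the MSA prior.
#' @param constraints a [ConstraintSet-class].
#' @return The state with `logLik` and `logPrior` filled.
#' @export
scoreState <- function(state, model, sequence, prior = c("noninfo", "msa"),
                       profile = NULL, constraints = model@constraints) {
  prior <- match.arg(prior)
  state@logLik <- totalLogLik(model, sequence, state@annotation)
  state@logPrior <- if (prior == "noninfo")
    logPriorNonInfo(state@annotation, constraints)
  else logPriorMsa(state@annotation, profile, constraints)
  state
}

.pickOne <- function(x) x[[sample.int(length(x), 1L)]]

# feasible move kinds for an annotation
.feasibleKinds <- function(ann) {
  c("switch",
    if (nBlocks(ann) >= 2L) c("boundary", "merge"),
    if (any(ann@lengths >= 2L)) "split")
}

#' Draw a Metropolis proposal
#'
#' One of four schemes, drawn uniformly among those feasible in the
#' current state (infeasible kinds are resampled by default, with the
#' kind probability `1 / #feasible` entering both proposal densities):
#' switch the type of a uniformly chosen block; move the boundary
#' between a uniformly chosen adjacent pair (new split point uniform
#' over the interior); split a uniformly chosen block of length >= 2
#' (left part keeps the type, right type uniform over all four); merge
#' a uniformly chosen adjacent pair into the left block's type.
#' Candidates that violate the hard constraints are still returned;
#' their prior is zero so they are always rejected.
#'
#' @param state a [ChainState-class].
#' @param constraints a [ConstraintSet-class] (used only to label
#'   feasibility; hard-constraint rejection happens at acceptance).
#' @param resampleInfeasible if `FALSE`, kinds are drawn uniformly from
#'   all four and an infeasible draw is returned as a `NULL` candidate
#'   (counted as a rejection by the caller).
#' @return A list: `kind`, `candidate` ([BlockAnnotation-class] or
#'   `NULL`), `logQFwd`, `logQRev`, `blocksOld` and `blocksNew` (index
#'   ranges of the affected blocks in the old and new annotation).
#' @export
proposeMove <- function(state, constraints = defaultConstraints(),
                        resampleInfeasible = TRUE) {
  ann <- state@annotation
  ty <- ann@types
  len <- ann@lengths
  M <- length(ty)
  kindLogP <- function(a) {
    if (resampleInfeasible) -log(length(.feasibleKinds(a))) else -log(4)
  }
  if (resampleInfeasible) {
    kind <- .pickOne(.feasibleKinds(ann))
  } else {
    kind <- .pickOne(c("switch", "boundary", "split", "merge"))
    feas <- kind %in% .feasibleKinds(ann)
    if (!feas)
      return(list(kind = kind, candidate = NULL, logQFwd = NA_real_,
                  logQRev = NA_real_, blocksOld = NULL, blocksNew = NULL))
  }
  if (kind == "switch") {
    m <- sample.int(M, 1L)
    newT <- .pickOne(setdiff(.STATES, ty[[m]]))
    nty <- ty; nty[[m]] <- newT
    cand <- BlockAnnotation(nty, len)
    list(kind = kind, candidate = cand,
         logQFwd = kindLogP(ann) - log(M) - log(3),
         logQRev = kindLogP(cand) - log(M) - log(3),
         blocksOld = c(m, m), blocksNew = c(m, m))
  } else if (kind == "boundary") {
    j <- sample.int(M - 1L, 1L)
    total <- len[[j]] + len[[j + 1L]]
    newLeft <- sample.int(total - 1L, 1L)
    nlen <- len; nlen[[j]] <- newLeft; nlen[[j + 1L]] <- total - newLeft
    cand <- BlockAnnotation(ty, nlen)
    list(kind = kind, candidate = cand,
         logQFwd = kindLogP(ann) - log(M - 1) - log(total - 1),
         logQRev = kindLogP(cand) - log(M - 1) - log(total - 1),
         blocksOld = c(j, j + 1L), blocksNew = c(j, j + 1L))
  } else if (kind == "split") {
    elig <- which(len >= 2L)
    j <- .pickOne(elig)
    left <- sample.int(len[[j]] - 1L, 1L)
    rightT <- .pickOne(.STATES)
    nty <- append(ty, rightT, after = j)
    nlen <- append(len, len[[j]] - left, after = j)
    nlen[[j]] <- left
    cand <- BlockAnnotation(nty, nlen)
    list(kind = kind, candidate = cand,
         logQFwd = kindLogP(ann) - log(length(elig)) -
           log(len[[j]] - 1) - log(4),
         logQRev = kindLogP(cand) - log(M),  # merge pair j among M pairs
         blocksOld = c(j, j), blocksNew = c(j, j + 1L))
  } else {  # merge
    j <- sample.int(M - 1L, 1L)
    total <- len[[j]] + len[[j + 1L]]
    nty <- ty[-(j + 1L)]
    nlen <- len; nlen[[j]] <- total; nlen <- nlen[-(j + 1L)]
    cand <- BlockAnnotation(nty, nlen)
    list(kind = kind, candidate = cand,
         logQFwd = kindLogP(ann) - log(M - 1),
         logQRev = kindLogP(cand) - log(sum(nlen >= 2L)) -
           log(total - 1) - log(4),
         blocksOld = c(j, j + 1L), blocksNew = c(j, j))
  }
}

# Local evaluation of the posterior delta restricted to the affected
# segments. Returns list(dLL, dPR) with dPR = -Inf for invalid
# candidates.
.localDelta <- function(model, sequence, state, proposal,
                        prior = "noninfo", profile = NULL,
                        constraints = model@constraints) {
  ann <- state@annotation
  cand <- proposal$candidate
  if (!isTRUE(c(validateAnnotation(cand, constraints))))
    return(list(dLL = 0, dPR = -Inf))
  blockLL <- function(a, idx) {
    ends <- cumsum(a@lengths)
    starts <- ends - a@lengths + 1L
    ll <- 0
    for (b in idx[[1L]]:idx[[2L]])
      ll <- ll + blockLogLik(model, substr(sequence, starts[[b]], ends[[b]]),
                             a@types[[b]])
    ll
  }
  dLL <- blockLL(cand, proposal$blocksNew) - blockLL(ann, proposal$blocksOld)
  dPR <- 0
  if (prior == "msa") {
    ends <- cumsum(ann@lengths)
    starts <- ends - ann@lengths + 1L
    lo <- starts[[proposal$blocksOld[[1L]]]]
    hi <- ends[[proposal$blocksOld[[2L]]]]
    posStates <- function(a) rep(.stateIndex(a@types), a@lengths)
    logq <- log(profile@q)
    idx <- lo:hi
    dPR <- sum(logq[cbind(idx, posStates(cand)[idx])]) -
      sum(logq[cbind(idx, posStates(ann)[idx])])
  }
  list(dLL = dLL, dPR = dPR)
}

#' Log Hastings ratio of a proposal
#'
#' `log r = log p(R | ann') + log p(ann') + log q(ann | ann') - log
#' p(R | ann) - log p(ann) - log q(ann' | ann)`. With `method =
#' "local"` the likelihood and prior differences are evaluated only on
#' the affected segments (the factorization over blocks makes this
#' exact); `method = "full"` recomputes both states from scratch.
#'
#' @inheritParams scoreState
#' @param proposal result of [proposeMove()].
#' @param method `"local"` or `"full"`.
#' @return The log Hastings ratio (may be `-Inf`).
#' @export
hastingsLogRatio <- function(model, sequence, state, proposal,
                             prior = c("noninfo", "msa"), profile = NULL,
                             constraints = model@constraints,
                             method = c("local", "full")) {
  prior <- match.arg(prior)
  method <- match.arg(method)
  if (is.null(proposal$candidate)) return(-Inf)
  dq <- proposal$logQRev - proposal$logQFwd
  if (method == "local") {
    d <- .localDelta(model, sequence, state, proposal, prior, profile,
                     constraints)
    return(d$dLL + d$dPR + dq)
  }
  lp <- function(a) {
    pr <- if (prior == "noninfo") logPriorNonInfo(a, constraints)
          else logPriorMsa(a, profile, constraints)
    if (!is.finite(pr)) return(-Inf)
    totalLogLik(model, sequence, a) + pr
  }
  lp(proposal$candidate) - lp(state@annotation) + dq
}

#' Accept or reject a proposal
#'
#' Accepts with probability `min(1, r)` where `r` is the Hastings ratio
#' evaluated locally on the affected segments; otherwise returns the
#' current state unchanged.
#'
#' @inheritParams hastingsLogRatio
#' @return A list: `state` (the new [ChainState-class]), `accepted`,
#'   `logRatio`.
#' @export
acceptMove <- function(state, proposal, model, sequence,
                       prior = c("noninfo", "msa"), profile = NULL,
                       constraints = model@constraints) {
  prior <- match.arg(prior)
  if (is.na(state@logLik))
    state <- scoreState(state, model, sequence, prior, profile, constraints)
  if (is.null(proposal$candidate))
    return(list(state = state, accepted = FALSE, logRatio = -Inf))
  d <- .localDelta(model, sequence, state, proposal, prior, profile,
                   constraints)
  logr <- d$dLL + d$dPR + proposal$logQRev - proposal$logQFwd
  if (is.finite(logr) && (logr >= 0 || log(stats::runif(1)) < logr)) {
    newState <- new("ChainState", annotation = proposal$candidate,
                    logLik = state@logLik + d$dLL,
                    logPrior = state@logPrior + d$dPR)
    list(state = newState, accepted = TRUE, logRatio = logr)
  } else {
    list(state = state, accepted = FALSE, logRatio = logr)
  }
}

#' Run a Metropolis chain and summarize its posterior
#'
#' Runs `nProposals` proposals from the all-coil initial state (or
#' `init`), discards `burnin`, and accumulates every retained
#' iteration's state (accepted or not) into the per-position marginal
#' matrix, the canonicalized block-count tallies, the log-posterior
#' trace, and the best-log-posterior (MAP) sample.
#'
#' @param model a [SecStructModel-class].
#' @param sequence amino-acid sequence (string).
#' @param prior `"noninfo"` or `"msa"`.
#' @param profile an [MsaProfile-class] (MSA prior only). A `NULL`
#'   profile with `prior = "msa"` falls back to NonInfo.
#' @param nProposals total proposals (default 1,000,000).
#' @param burnin discarded initial iterations (default 10,000).
#' @param thin store every `thin`-th retained log-posterior in the
#'   trace.
#' @param seed integer seed for reproducibility (sets R's RNG).
#' @param init optional initial [BlockAnnotation-class] (must be
#'   valid).
#' @param constraints a [ConstraintSet-class]; defaults to the model's.
#' @param resampleInfeasible resample infeasible move kinds (default)
#'   rather than counting them as rejections.
#' @param trackStates tally visited block-list state frequencies
#'   (intended for small L; capped at `maxStates` distinct states).
#' @param keepEvery if positive, retain every `keepEvery`-th sampled
#'   annotation in `samples`.
#' @param maxStates cap on distinct tracked states.
#' @return A [PosteriorSummary-class].
#' @export
runChain <- function(model, sequence, prior = c("noninfo", "msa"),
                     profile = NULL, nProposals = 1e6, burnin = 1e4,
                     thin = 1L, seed = NULL, init = NULL,
                     constraints = model@constraints,
                     resampleInfeasible = TRUE, trackStates = FALSE,
                     keepEvery = 0L, maxStates = 100000L) {
  prior <- match.arg(prior)
  if (prior == "msa" && is.null(profile)) prior <- "noninfo"
  stopifnot(nProposals > burnin)
  if (!is.null(seed)) set.seed(seed)
  L <- nchar(sequence)
  if (is.null(init)) init <- BlockAnnotation("C", L)
  stopifnot(sum(init@lengths) == L)
  if (!isTRUE(c(validateAnnotation(init, constraints))))
    .stopf("initial annotation violates the hard constraints")
  seg <- segmentLogLik(model, sequence)
  logq <- .priorPosMatrix(L, prior, profile)
  cc <- .constraintCodes(constraints)
  res <- .chain_run(unname(seg[.STATES]), logq, cc$minLen, cc$forbid,
                    if (is.na(cc$termIdx)) -1L else cc$termIdx - 1L,
                    .stateIndex(init@types) - 1L, init@lengths,
                    as.integer(nProposals), as.integer(burnin),
                    as.integer(thin), resampleInfeasible, trackStates,
                    as.integer(keepEvery), as.integer(maxStates))
  marg <- res$marginals
  colnames(marg) <- .STATES
  mapAnn <- BlockAnnotation(.STATES[res$bestTy + 1L], res$bestLen)
  byType <- res$blockByType
  names(byType) <- .STATES
  samples <- lapply(res$samples, function(s)
    BlockAnnotation(.STATES[s$ty + 1L], s$len))
  new("PosteriorSummary",
      marginals = marg,
      map = list(annotation = mapAnn, logPost = res$bestLogPost,
                 iteration = res$bestIter),
      trace = res$trace,
      blockCounts = list(total = res$blockTotal, byType = byType),
      stateFreq = if (res$stateFreqOverflow) {
        warning("state tracking overflowed maxStates; frequencies dropped")
        numeric(0)
      } else res$stateFreq,
      diagnostics = list(
        acceptanceRate = res$nAccept / nProposals,
        validityRate = res$nValid / nProposals,
        nResampled = res$nResampled,
        nInfeasibleRejected = res$nInfeasibleRejected,
        nRetained = res$nRetained, nProposals = nProposals,
        burnin = burnin, seed = seed, prior = prior,
        finalLogPost = res$finalLogPost),
      samples = samples)
}
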