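# Posterior point estimates and summaries: MAP (best retained sample),
# MP (per-position argmax of the marginals), block-count posteriors,
# and the marginal-margin statistics used to judge prediction
# confidence.

#' Maximum a posteriori estimate
#'
#' The retained sample with the highest unnormalized log posterior,
#' canonicalized for reporting. Ties are broken by earliest iteration
#' (the chain records the first sample attaining the maximum).
#'
#' @param summary a [PosteriorSummary-class].
#' @return A canonical [BlockAnnotation-class].
#' @export
mapEstimate <- function(summary) {
  stopifnot(is(summary, "PosteriorSummary"))
  if (!length(summary@map) || is.null(summary@map$annotation))
    .stopf("summary contains no retained samples")
  canonicalizeAnnotation(summary@map$annotation)
}

# MP tie-break preference: C > T > E > H (fixed, documented).
.MP_ORDER <- c("C", "T", "E", "H")

#' Marginal probability estimate
#'
#' Selects the most likely state at each position from the posterior
#' marginal matrix. Exact ties are broken by the fixed preference order
#' C > T > E > H.
#'
#' @param summary a [PosteriorSummary-class], or an L x 4 marginal
#'   matrix with columns `H,E,T,C`.
#' @return The per-position state string.
#' @export
mpEstimate <- function(summary) {
  marg <- if (is(summary, "PosteriorSummary")) summary@marginals else summary
  stopifnot(is.matrix(marg), ncol(marg) == 4L)
  m <- marg[, .MP_ORDER, drop = FALSE]
  paste(.MP_ORDER[max.col(m, ties.method = "first")], collapse = "")
}

#' Posterior distributions of block counts
#'
#' Empirical distributions, over retained samples, of the canonical
#' number of blocks in total and per type (adjacent same-type blocks
#' merged before counting).
#'
#' @param summary a [PosteriorSummary-class].
#' @return List with `total` (named probability vector over M) and
#'   `byType` (list of four named probability vectors).
#' @export
blockCountPosterior <- function(summary) {
  stopifnot(is(summary, "PosteriorSummary"))
  bc <- summary@blockCounts
  if (!length(bc$total)) .stopf("summary contains no retained samples")
  bc
}

#' Margin statistics of the marginal matrix
#'
#' For each position, the margin is the difference between the
#' predicted state's marginal probability and the highest remaining
#' probability: at correctly predicted positions this separates the
#' correct state from its best competitor; at wrongly predicted
#' positions it separates the wrong prediction from the next highest
#' state. Means and standard deviations are reported per true state,
#' split by correct/wrong.
#'
#' @param marginals L x 4 marginal matrix (columns `H,E,T,C`).
#' @param prediction predicted state string (defaults to the MP
#'   estimate of `marginals`).
#' @param truth true state string of the same length.
#' @return Data frame with columns `state`, `outcome` (`correct` or
#'   `wrong`), `mean`, `sd`, `n`.
#' @export
marginStatistics <- function(marginals, prediction = mpEstimate(marginals),
                             truth) {
  stopifnot(is.matrix(marginals), ncol(marginals) == 4L)
  L <- nrow(marginals)
  if (nchar(prediction) != L || nchar(truth) != L)
    .stopf("prediction/truth length must match the marginal matrix")
  pred <- strsplit(prediction, "")[[1]]
  tru <- strsplit(truth, "")[[1]]
  pi <- .stateIndex(pred)
  pPred <- marginals[cbind(seq_len(L), pi)]
  pBest2 <- vapply(seq_len(L), function(l) max(marginals[l, -pi[[l]]]),
                   numeric(1))
  margin <- pPred - pBest2
  correct <- pred == tru
  out <- expand.grid(state = .STATES, outcome = c("correct", "wrong"),
                     stringsAsFactors = FALSE)
  out$mean <- NA_real_
  out$sd <- NA_real_
  out$n <- 0L
  for (i in seq_len(nrow(out))) {
    sel <- tru == out$state[[i]] &
      (if (out$outcome[[i]] == "correct") correct else !correct)
    out$n[[i]] <- sum(sel)
    if (any(sel)) {
      out$mean[[i]] <- mean(margin[sel])
      out$sd[[i]] <- stats::sd(margin[sel])
    }
  }
  out
}
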