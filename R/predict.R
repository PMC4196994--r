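# High-level prediction wrapper tying the sampler and estimators
# together for one sequence.

#' Predict secondary structure for one sequence
#'
#' Runs the Metropolis sampler under the chosen prior and summarizes
#' the posterior with the marginal-probability (MP) or maximum a
#' posteriori (MAP) estimator. With `prior = "msa"` but no profile the
#' prediction falls back to the NonInfo prior, mirroring the treatment
#' of query sequences without alignment evidence.
#'
#' @inheritParams runChain
#' @param estimator `"mp"` (per-position argmax of the marginals) or
#'   `"map"` (best retained sample).
#' @param ... passed to [runChain()].
#' @return List: `prediction` (state string), `summary`
#'   ([PosteriorSummary-class]), `report` (data frame with 1-based
#'   `pos`, `residue`, `state`, and the four marginal probabilities).
#' @export
predictSecStruct <- function(model, sequence, prior = c("noninfo", "msa"),
                             profile = NULL, estimator = c("mp", "map"),
                             nProposals = 1e6, burnin = 1e4, seed = NULL,
                             ...) {
  prior <- match.arg(prior)
  estimator <- match.arg(estimator)
  summary <- runChain(model, sequence, prior = prior, profile = profile,
                      nProposals = nProposals, burnin = burnin,
                      seed = seed, ...)
  prediction <- if (estimator == "mp") mpEstimate(summary)
                else blocksToLinear(mapEstimate(summary))
  marg <- summary@marginals
  report <- data.frame(pos = seq_len(nchar(sequence)),
                       residue = strsplit(sequence, "")[[1]],
                       state = strsplit(prediction, "")[[1]],
                       pH = marg[, "H"], pE = marg[, "E"],
                       pT = marg[, "T"], pC = marg[, "C"])
  list(prediction = prediction, summary = summary, report = report)
}

#' Plot marginal-probability curves
#'
#' One curve per state across positions, the Bayesian confidence view
#' of a prediction; optionally annotated with the true states.
#'
#' @param summary a [PosteriorSummary-class] or L x 4 marginal matrix.
#' @param truth optional true state string.
#' @return A `ggplot` object (requires the ggplot2 package).
#' @export
plotMarginals <- function(summary, truth = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    .stopf("plotMarginals requires the ggplot2 package")
  marg <- if (is(summary, "PosteriorSummary")) summary@marginals else summary
  L <- nrow(marg)
  df <- data.frame(pos = rep(seq_len(L), 4L),
                   state = rep(.STATES, each = L),
                   prob = as.vector(marg))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$prob,
                                        color = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position", y = "marginal probability",
                  color = "state") +
    ggplot2::ylim(0, 1)
  if (!is.null(truth)) {
    tdf <- data.frame(pos = seq_len(L),
                      state = strsplit(truth, "")[[1]])
    p <- p + ggplot2::geom_rug(data = tdf,
                               ggplot2::aes(x = .data$pos,
                                            color = .data$state),
                               inherit.aes = FALSE, sides = "t")
  }
  p
}
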