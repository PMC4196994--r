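# Accessor generics and show methods for the central classes.

#' @rdname BlockAnnotation-class
#' @param object,x a `BlockAnnotation`.
#' @export
setGeneric("blockTypes", function(x) standardGeneric("blockTypes"))
#' @rdname BlockAnnotation-class
#' @export
setMethod("blockTypes", "BlockAnnotation", function(x) x@types)

#' @rdname BlockAnnotation-class
#' @export
setGeneric("blockLengths", function(x) standardGeneric("blockLengths"))
#' @rdname BlockAnnotation-class
#' @export
setMethod("blockLengths", "BlockAnnotation", function(x) x@lengths)

#' @rdname BlockAnnotation-class
#' @export
setGeneric("nBlocks", function(x) standardGeneric("nBlocks"))
#' @rdname BlockAnnotation-class
#' @export
setMethod("nBlocks", "BlockAnnotation", function(x) length(x@types))

#' @rdname BlockAnnotation-class
#' @export
setMethod("length", "BlockAnnotation", function(x) sum(x@lengths))

#' @rdname BlockAnnotation-class
#' @export
setMethod("show", "BlockAnnotation", function(object) {
  cat(sprintf("BlockAnnotation: L = %d, M = %d\n  %s\n",
              sum(object@lengths), length(object@types),
              paste0(object@types, object@lengths, collapse = " ")))
})

#' @rdname ConstraintSet-class
#' @param object a `ConstraintSet`.
#' @export
setMethod("show", "ConstraintSet", function(object) {
  fa <- apply(object@forbiddenAdjacency, 1L,
              function(p) paste0(p[1], "->", p[2]))
  cat("ConstraintSet\n",
      " min lengths: ", paste0(.STATES, ":", object@minLengths[.STATES],
                               collapse = " "), "\n",
      " forbidden adjacency: ",
      if (length(fa)) paste(fa, collapse = ", ") else "none", "\n",
      " terminal type: ", object@terminalType, "\n", sep = "")
})

#' @rdname SecStructModel-class
#' @param object a `SecStructModel`.
#' @export
setMethod("show", "SecStructModel", function(object) {
  nb <- object@meta$blockCounts
  cat("SecStructModel (Dirichlet-multinomial block likelihoods)\n")
  cat(sprintf("  alpha = %g, helix mixture weight = %g\n",
              object@alpha, object@mixtureWeight))
  if (!is.null(nb))
    cat("  trained on blocks: ",
        paste0(names(nb), ":", nb, collapse = " "), "\n", sep = "")
  for (fam in names(object@tables)) {
    nctx <- sum(vapply(object@tables[[fam]],
                       function(s) length(ls(s$counts)), integer(1)))
    cat(sprintf("  %-6s %d slots, %d observed contexts\n", fam,
                length(object@tables[[fam]]), nctx))
  }
})

#' @rdname MsaProfile-class
#' @param object,x an `MsaProfile`.
#' @export
setMethod("show", "MsaProfile", function(object) {
  cat(sprintf("MsaProfile: L = %d positions, depth range [%d, %d]\n",
              nrow(object@counts), min(object@depth, 0L),
              max(object@depth, 0L)))
})

#' @rdname MsaProfile-class
#' @export
setMethod("length", "MsaProfile", function(x) nrow(x@counts))

#' @rdname MsaProfile-class
#' @export
setGeneric("msaCounts", function(x) standardGeneric("msaCounts"))
#' @rdname MsaProfile-class
#' @export
setMethod("msaCounts", "MsaProfile", function(x) x@counts)

#' @rdname MsaProfile-class
#' @export
setGeneric("msaDepth", function(x) standardGeneric("msaDepth"))
#' @rdname MsaProfile-class
#' @export
setMethod("msaDepth", "MsaProfile", function(x) x@depth)

#' @rdname PosteriorSummary-class
#' @param x,object a `PosteriorSummary`.
#' @export
setGeneric("marginals", function(x) standardGeneric("marginals"))
#' @rdname PosteriorSummary-class
#' @export
setMethod("marginals", "PosteriorSummary", function(x) x@marginals)

#' @rdname PosteriorSummary-class
#' @export
setGeneric("diagnostics", function(x) standardGeneric("diagnostics"))
#' @rdname PosteriorSummary-class
#' @export
setMethod("diagnostics", "PosteriorSummary", function(x) x@diagnostics)

#' @rdname PosteriorSummary-class
#' @export
setMethod("show", "PosteriorSummary", function(object) {
  d <- object@diagnostics
  cat(sprintf("PosteriorSummary: L = %d, %d retained iterations\n",
              nrow(object@marginals), d$nRetained))
  cat(sprintf("  MAP log posterior = %.4f (M = %d)\n", object@map$logPost,
              nBlocks(object@map$annotation)))
  cat(sprintf("  acceptance rate = %.3f, proposal validity rate = %.3f\n",
              d$acceptanceRate, d$validityRate))
})

#' @rdname ConfusionSummary-class
#' @param object a `ConfusionSummary`.
#' @export
setMethod("show", "ConfusionSummary", function(object) {
  cat("ConfusionSummary (rows = predicted, columns = actual)\n")
  cat("counts:\n"); print(object@counts)
  cat("recall (columns sum to 100):\n"); print(round(object@recall, 1))
  cat("precision (rows sum to 100):\n"); print(round(object@precision, 1))
})
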