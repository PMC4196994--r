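# Conversions between the block and linear parameterizations, and the
# hard structural-validity predicate.

#' Expand a block annotation to the linear per-residue string
#'
#' Position l of the result carries the type of the block covering l,
#' so the string length equals the sum of block lengths.
#'
#' @param annotation a [BlockAnnotation-class].
#' @return A single string over `{H,E,T,C}`.
#' @examples
#' blocksToLinear(BlockAnnotation(c("C", "H", "C"), c(1, 3, 1)))  # "CHHHC"
#' @export
blocksToLinear <- function(annotation) {
  stopifnot(is(annotation, "BlockAnnotation"))
  paste(rep(annotation@types, annotation@lengths), collapse = "")
}

#' Parse a linear state string into canonical blocks
#'
#' Maximal runs of identical states become blocks; the result never
#' contains adjacent same-type blocks.
#'
#' @param linear a non-empty string over `{H,E,T,C}`.
#' @return A [BlockAnnotation-class].
#' @examples
#' linearToBlocks("CHHHC")
#' @export
linearToBlocks <- function(linear) {
  if (!is.character(linear) || length(linear) != 1L || !nzchar(linear))
    .stopf("linear annotation must be a single non-empty string")
  ch <- strsplit(linear, "", fixed = TRUE)[[1]]
  if (!all(ch %in% .STATES))
    .stopf("state string contains characters outside {H,E,T,C}: %s",
           paste(unique(ch[!ch %in% .STATES]), collapse = ""))
  r <- rle(ch)
  BlockAnnotation(r$values, r$lengths)
}

#' Merge adjacent same-type blocks
#'
#' The sampler's split move can create adjacent blocks of the same type;
#' canonical form merges them, leaving the linear image unchanged. Used
#' for reporting and block-count summaries.
#'
#' @param annotation a [BlockAnnotation-class].
#' @return A canonical [BlockAnnotation-class].
#' @export
canonicalizeAnnotation <- function(annotation) {
  stopifnot(is(annotation, "BlockAnnotation"))
  ty <- annotation@types
  if (length(ty) == 1L) return(annotation)
  grp <- cumsum(c(TRUE, ty[-1L] != ty[-length(ty)]))
  BlockAnnotation(ty[!duplicated(grp)],
                  as.integer(tapply(annotation@lengths, grp, sum)))
}

#' Check an annotation against the hard structural constraints
#'
#' Tests the rules encoded in a [ConstraintSet-class]: required terminal
#' type for first and last block, forbidden ordered adjacencies, and
#' per-type minimum block lengths. Rules are applied to the block list
#' as given (adjacent same-type blocks are each held to the minimum
#' individually).
#'
#' @param annotation a [BlockAnnotation-class].
#' @param constraints a [ConstraintSet-class].
#' @return A logical with attribute `violations`, a character vector
#'   naming each failed rule (empty when valid).
#' @examples
#' validateAnnotation(BlockAnnotation("H", 3), defaultConstraints())
#' @export
validateAnnotation <- function(annotation, constraints = defaultConstraints()) {
  stopifnot(is(annotation, "BlockAnnotation"), is(constraints, "ConstraintSet"))
  ty <- annotation@types
  len <- annotation@lengths
  M <- length(ty)
  viol <- character()
  tt <- constraints@terminalType
  if (!is.na(tt)) {
    if (ty[1L] != tt)
      viol <- c(viol, sprintf("terminal: first block is %s, not %s", ty[1L], tt))
    if (ty[M] != tt)
      viol <- c(viol, sprintf("terminal: last block is %s, not %s", ty[M], tt))
  }
  fa <- constraints@forbiddenAdjacency
  if (M > 1L && nrow(fa)) {
    pairs <- paste(ty[-M], ty[-1L])
    bad <- pairs %in% paste(fa[, 1L], fa[, 2L])
    if (any(bad))
      viol <- c(viol, sprintf("adjacency: %s block followed by %s",
                              ty[-M][bad], ty[-1L][bad]))
  }
  short <- len < constraints@minLengths[ty]
  if (any(short))
    viol <- c(viol, sprintf("min-length: %s block of length %d (minimum %d)",
                            ty[short], len[short],
                            constraints@minLengths[ty[short]]))
  structure(length(viol) == 0L, violations = viol)
}

# Fast validity on integer-coded types (1=H,2=E,3=T,4=C); used by the
# oracle and the R-level sampler where the S4 overhead matters.
.validFast <- function(tyi, len, minLen, forbid, termIdx) {
  M <- length(tyi)
  if (!is.na(termIdx) && (tyi[1L] != termIdx || tyi[M] != termIdx)) return(FALSE)
  if (any(len < minLen[tyi])) return(FALSE)
  if (M > 1L && any(forbid[cbind(tyi[-M], tyi[-1L])])) return(FALSE)
  TRUE
}

# ConstraintSet -> integer-coded pieces for .validFast and the C++ chain.
.constraintCodes <- function(constraints) {
  forbid <- matrix(FALSE, 4L, 4L)
  fa <- constraints@forbiddenAdjacency
  if (nrow(fa))
    forbid[cbind(.stateIndex(fa[, 1L]), .stateIndex(fa[, 2L]))] <- TRUE
  list(minLen = as.integer(constraints@minLengths[.STATES]),
       forbid = forbid,
       termIdx = if (is.na(constraints@terminalType)) NA_integer_
                 else .stateIndex(constraints@terminalType))
}
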