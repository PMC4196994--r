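# Block log-likelihoods: each block's probability is a product of
# position-specific Dirichlet-multinomial emissions under its type's
# dependency template; helix blocks mix a forward (N-capping) and a
# backward (C-capping) factorization. All computation is in log space.

# log emission probability at `pos` (1-based in `codes`) under `slot`,
# with context taken at pos + offsets. Unknown residues emit log(1/20);
# contexts containing an unknown back off to the slot's unconditional
# table (key "").
.posLogProb <- function(slot, codes, pos, alpha) {
  res <- codes[[pos]]
  if (res == 21L) return(log(1 / 20))
  off <- slot$offsets
  key <- .NOCTX
  if (length(off)) {
    ctx <- codes[pos + off]
    if (all(ctx < 21L)) key <- paste(.AA20[ctx], collapse = "")
  }
  v <- slot$counts[[key]]
  if (is.null(v)) return(log(alpha / (20 * alpha)))
  log((v[[res]] + alpha) / (sum(v) + 20 * alpha))
}

# Log-likelihood of one block's residues under a single table family.
.familyLogLik <- function(model, fam, codes) {
  template <- model@templates[[fam]]
  family <- model@tables[[fam]]
  K <- length(template@slots)
  backward <- template@direction == "backward"
  len <- length(codes)
  ll <- 0
  for (pos in seq_len(len)) {
    k <- if (backward) min(len - pos + 1L, K) else min(pos, K)
    ll <- ll + .posLogProb(family[[k]], codes, pos, model@alpha)
  }
  ll
}

#' Log-likelihood of a block's residues given its type
#'
#' Strand, coil and turn blocks are scored as products of per-slot
#' smoothed emission probabilities under their templates (turns under
#' the table set of the block's length class). Helix blocks are scored
#' as the mixture `w * forward + (1 - w) * backward`. Slots beyond the
#' block length are simply ignored.
#'
#' @param model a [SecStructModel-class].
#' @param residues the block's residues (string).
#' @param type block type, one of `"H","E","T","C"`.
#' @return The log-probability of the residues.
#' @examples
#' blockLogLik(emptyModel(), "MKV", "E")  # 3 * log(1/20)
#' @export
blockLogLik <- function(model, residues, type) {
  stopifnot(is(model, "SecStructModel"), nchar(residues) >= 1L,
            type %in% .STATES)
  codes <- .aaCodes(residues)
  fams <- .familyFor(type, length(codes))
  if (length(fams) == 1L) return(.familyLogLik(model, fams, codes))
  w <- model@mixtureWeight
  fwd <- .familyLogLik(model, fams[[1L]], codes)
  if (w == 1) return(fwd)
  bwd <- .familyLogLik(model, fams[[2L]], codes)
  if (w == 0) return(bwd)
  .logSumExp(c(log(w) + fwd, log1p(-w) + bwd))
}

#' Joint log-likelihood of a sequence under a block annotation
#'
#' The joint probability factorizes as a product over blocks;
#' conditioning never crosses a block boundary, so splitting a block
#' changes the value even when types match.
#'
#' @param model a [SecStructModel-class].
#' @param sequence amino-acid sequence (string).
#' @param annotation a [BlockAnnotation-class] whose lengths sum to the
#'   sequence length.
#' @return The log-probability of the sequence given the annotation.
#' @export
totalLogLik <- function(model, sequence, annotation) {
  stopifnot(is(annotation, "BlockAnnotation"))
  L <- nchar(sequence)
  if (sum(annotation@lengths) != L)
    .stopf("annotation covers %d positions but sequence has %d",
           sum(annotation@lengths), L)
  ends <- cumsum(annotation@lengths)
  starts <- ends - annotation@lengths + 1L
  ll <- 0
  for (b in seq_along(ends))
    ll <- ll + blockLogLik(model, substr(sequence, starts[[b]], ends[[b]]),
                           annotation@types[[b]])
  ll
}

# ---- Per-segment log-likelihood matrices -------------------------------
# For a fixed sequence, precompute log p(R[s..e] | type) for every
# segment and type. Because interior slots condition only on fixed
# relative offsets, their contribution is a prefix (or suffix) sum and
# the whole L x L table costs O(L^2). These matrices are the likelihood
# cache behind the sampler's local Hastings evaluation and the oracle.

# Forward family -> L x L matrix (row = start, col = end; NA below
# the diagonal).
.segMatForward <- function(model, fam, codes) {
  template <- model@templates[[fam]]
  family <- model@tables[[fam]]
  alpha <- model@alpha
  K <- length(template@slots)
  L <- length(codes)
  # interior contribution f[p], defined for p >= K
  f <- numeric(L)
  if (L >= K)
    for (p in K:L) f[[p]] <- .posLogProb(family[[K]], codes, p, alpha)
  Fc <- cumsum(f)
  # explicit slot values g[k, s] at position s + k - 1
  out <- matrix(NA_real_, L, L)
  nk <- min(K - 1L, L)
  for (s in seq_len(L)) {
    dmax <- L - s + 1L
    ce <- 0
    d <- 1L
    # explicit slots
    while (d <= min(nk, dmax)) {
      ce <- ce + .posLogProb(family[[d]], codes, s + d - 1L, alpha)
      out[s, s + d - 1L] <- ce
      d <- d + 1L
    }
    if (dmax >= K) {
      e <- (s + K - 1L):L
      out[s, e] <- ce + Fc[e] - Fc[[s + K - 2L]]
    }
  }
  out
}

# Backward family (helix C-capping): slots anchored at the segment end.
.segMatBackward <- function(model, fam, codes) {
  template <- model@templates[[fam]]
  family <- model@tables[[fam]]
  alpha <- model@alpha
  K <- length(template@slots)
  L <- length(codes)
  # interior contribution f[p], defined for p <= L - (K - 1)
  f <- numeric(L + 1L)
  if (L >= K)
    for (p in 1:(L - K + 1L)) f[[p]] <- .posLogProb(family[[K]], codes, p, alpha)
  Sc <- rev(cumsum(rev(f)))  # Sc[p] = sum_{j >= p} f[j]
  out <- matrix(NA_real_, L, L)
  nk <- min(K - 1L, L)
  for (e in seq_len(L)) {
    dmax <- e
    ce <- 0
    d <- 1L
    while (d <= min(nk, dmax)) {
      ce <- ce + .posLogProb(family[[d]], codes, e - d + 1L, alpha)
      out[e - d + 1L, e] <- ce
      d <- d + 1L
    }
    if (dmax >= K) {
      s <- 1:(e - K + 1L)
      out[s, e] <- ce + Sc[s] - Sc[[e - K + 2L]]
    }
  }
  out
}

# Direct (slot-walk) fill of segments with length d in `lens`, used for
# the short turn length classes.
.segFillDirect <- function(out, model, famOf, codes, lens) {
  L <- length(codes)
  alpha <- model@alpha
  for (d in lens) {
    if (d > L) next
    fam <- famOf(d)
    template <- model@templates[[fam]]
    family <- model@tables[[fam]]
    K <- length(template@slots)
    for (s in 1:(L - d + 1L)) {
      ll <- 0
      for (pos in seq_len(d))
        ll <- ll + .posLogProb(family[[min(pos, K)]], codes, s + pos - 1L, alpha)
      out[s, s + d - 1L] <- ll
    }
  }
  out
}

#' Per-segment log-likelihood matrices for a sequence
#'
#' Precomputes `log p(R[s..e] | type)` for all `1 <= s <= e <= L` and
#' each of the four block types (helix entries are already the
#' forward/backward mixture). Row = segment start, column = segment end.
#'
#' @param model a [SecStructModel-class].
#' @param sequence amino-acid sequence (string).
#' @return Named list of four L x L matrices (`H`, `E`, `T`, `C`).
#' @export
segmentLogLik <- function(model, sequence) {
  codes <- .aaCodes(sequence)
  fwd <- .segMatForward(model, "H_fwd", codes)
  bwd <- .segMatBackward(model, "H_bwd", codes)
  w <- model@mixtureWeight
  H <- if (w == 1) fwd else if (w == 0) bwd else {
    # elementwise log(w e^fwd + (1-w) e^bwd), stably
    m <- pmax(fwd, bwd)
    m + log(w * exp(fwd - m) + (1 - w) * exp(bwd - m))
  }
  Tm <- .segMatForward(model, "T5", codes)
  Tm <- .segFillDirect(Tm, model,
                       function(d) if (d <= 3L) "T3" else "T4",
                       codes, 1:4)
  list(H = H,
       E = .segMatForward(model, "E", codes),
       T = Tm,
       C = .segMatForward(model, "C", codes))
}
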