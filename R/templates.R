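# Dependency templates: which in-block positions each emission
# distribution conditions on, per block type. These encode the local
# socket packing motifs of each secondary-structure type as conditioning
# sets; they are data, not code, so alternative readings can be tried
# without touching the likelihood.

#' Default dependency templates
#'
#' Returns the template set used throughout the package, one family per
#' block type (helix has a forward and a mirrored backward family to
#' capture N- and C-terminal capping signals; turns have one family per
#' length class 3, 4 and >= 5):
#'
#' * `H_fwd`: slot 1 unconditional; slot 2 on -1; slots 3 and 4 on
#'   (-1, -2); interior (>= 5) on (-1, -3, -4) - one helical turn back.
#' * `H_bwd`: exact mirror image anchored at the C-terminus.
#' * `E`: slots 1 and 2 unconditional; slots 3 and 4 on -2 (the
#'   same-side neighbor on a strand); slot 5 and interior on (-2, -4).
#' * `C`: slot 1 unconditional; slot 2 on -1; interior on (-1, -2).
#' * `T3`, `T4`, `T5`: slot 1 unconditional; later slots on the in-block
#'   part of (-1, -2); `T5` interior reuses its last slot.
#'
#' The conditioning sets beyond the directly documented helix interior
#' are reconstructed from the socket geometry of each motif and are
#' configurable data.
#'
#' @return Named list of [DependencyTemplate-class] objects with names
#'   `H_fwd, H_bwd, E, C, T3, T4, T5`.
#' @examples
#' defaultTemplates()$H_fwd
#' @export
defaultTemplates <- function() {
  list(
    H_fwd = DependencyTemplate("H", "forward",
      list(integer(), -1L, c(-1L, -2L), c(-1L, -2L), c(-1L, -3L, -4L))),
    H_bwd = DependencyTemplate("H", "backward",
      list(integer(), 1L, c(1L, 2L), c(1L, 2L), c(1L, 3L, 4L))),
    E = DependencyTemplate("E", "forward",
      list(integer(), integer(), -2L, -2L, c(-2L, -4L), c(-2L, -4L))),
    C = DependencyTemplate("C", "forward",
      list(integer(), -1L, c(-1L, -2L))),
    T3 = DependencyTemplate("T", "forward",
      list(integer(), -1L, c(-1L, -2L))),
    T4 = DependencyTemplate("T", "forward",
      list(integer(), -1L, c(-1L, -2L), c(-1L, -2L))),
    T5 = DependencyTemplate("T", "forward",
      list(integer(), -1L, c(-1L, -2L), c(-1L, -2L), c(-1L, -2L)))
  )
}

# Family name for a block of the given type/length under a template set
# (helix resolves to the pair c("H_fwd", "H_bwd")).
.familyFor <- function(type, blockLength) {
  switch(type,
         H = c("H_fwd", "H_bwd"),
         E = "E",
         C = "C",
         T = if (blockLength <= 3L) "T3" else if (blockLength == 4L) "T4" else "T5")
}

# Slot index serving 1-based in-block position `pos` (from the
# N-terminus) in a block of length `len` under `template`.
.slotAt <- function(template, len, pos) {
  K <- length(template@slots)
  if (template@direction == "forward") min(pos, K) else min(len - pos + 1L, K)
}

#' Conditioning context for a slot
#'
#' Resolves the ordered tuple of conditioning residues for the emission
#' at a given in-block position under a template. Offsets are applied to
#' the (1-based, N-terminal) position; for backward templates the slot
#' is selected by the distance from the C-terminus.
#'
#' @param template a [DependencyTemplate-class].
#' @param blockLength the block's length.
#' @param position 1-based position within the block (from the
#'   N-terminus).
#' @param residues the block's residues, a string of length
#'   `blockLength`.
#' @return Character vector of conditioning residues in template offset
#'   order (empty for unconditional slots).
#' @examples
#' contextKey(defaultTemplates()$H_fwd, 5, 5, "MKVLA")  # c("L","K","M")
#' @export
contextKey <- function(template, blockLength, position, residues) {
  stopifnot(is(template, "DependencyTemplate"),
            position >= 1L, position <= blockLength,
            nchar(residues) == blockLength)
  off <- template@slots[[.slotAt(template, blockLength, position)]]
  if (!length(off)) return(character())
  idx <- position + off
  if (any(idx < 1L | idx > blockLength))
    .stopf("template invariant violated: conditioning offset escapes the block")
  substring(residues, idx, idx)
}

# Number of distinct conditioning contexts a slot can take.
.slotContexts <- function(template, k) 20L^length(template@slots[[k]])

#' Serialize templates to a YAML mapping
#'
#' @param templates named list of [DependencyTemplate-class] objects.
#' @param path file to write; when `NULL` the YAML text is returned.
#' @return `path` invisibly, or the YAML string.
#' @export
templatesToYaml <- function(templates, path = NULL) {
  x <- lapply(templates, function(tp)
    list(type = tp@type, direction = tp@direction,
         slots = lapply(tp@slots, as.integer)))
  txt <- yaml::as.yaml(x)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Read templates from a YAML mapping
#'
#' @param path file or YAML string produced by [templatesToYaml()].
#' @return Named list of [DependencyTemplate-class] objects.
#' @export
templatesFromYaml <- function(path) {
  x <- if (file.exists(path)) yaml::read_yaml(path) else yaml::yaml.load(path)
  out <- lapply(x, function(tp)
    DependencyTemplate(tp$type, tp$direction,
                       lapply(tp$slots, as.integer)))
  names(out) <- names(x)
  out
}
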