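# Readers and writers: FASTA sequences (via Biostrings), the 3-line
# paired sequence/structure format, a minimal classic DSSP reader with
# the 8 -> 4 state reduction, MSA evidence (aligned structure strings
# or a count TSV), model files, and prediction reports.

#' Read amino-acid sequences from FASTA
#'
#' Residues are upper-cased; letters outside the 20 standard one-letter
#' codes are mapped to the unknown code `X` with a warning.
#'
#' @param path FASTA file.
#' @return A named character vector of residue strings (one element per
#'   record, names from headers).
#' @export
readFastaAA <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) .stopf("malformed FASTA '%s': %s",
                                             path, conditionMessage(e)))
  if (!length(set)) .stopf("FASTA '%s' contains no records", path)
  if (any(Biostrings::width(set) == 0L))
    .stopf("FASTA '%s' has a header with no sequence", path)
  out <- character(length(set))
  nMapped <- 0L
  for (i in seq_along(set)) {
    cl <- .cleanResidues(as.character(set[[i]]))
    out[[i]] <- cl$residues
    nMapped <- nMapped + cl$nMapped
  }
  if (nMapped > 0L)
    warning(nMapped, " non-standard residue(s) mapped to the unknown code 'X'")
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write sequences to FASTA
#'
#' @param sequences named character vector of residue strings.
#' @param path output file.
#' @export
writeFastaAA <- function(sequences, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(sequences))
    writeLines(c(paste0(">", names(sequences)[[i]]), sequences[[i]]), con)
  invisible(path)
}

#' Read a paired sequence/structure file
#'
#' The canonical training format: records of three lines - a `>id`
#' header, the amino-acid sequence, and the 4-state structure string of
#' equal length.
#'
#' @param path paired file.
#' @return Data frame with columns `id`, `sequence`, `structure`.
#' @export
readPaired <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) .stopf("paired file '%s' is empty", path)
  hdr <- grepl("^>", lines)
  if (!hdr[[1L]] || length(lines) %% 3L != 0L || !all(hdr[seq(1L, length(lines), 3L)]))
    .stopf("paired file '%s' is not in 3-line (>id / sequence / structure) format",
           path)
  ids <- sub("^>", "", sub("\\s.*$", "", lines[seq(1L, length(lines), 3L)]))
  seqs <- toupper(lines[seq(2L, length(lines), 3L)])
  sss <- toupper(lines[seq(3L, length(lines), 3L)])
  for (i in seq_along(ids)) {
    if (nchar(seqs[[i]]) != nchar(sss[[i]]))
      .stopf("record '%s': sequence length %d != structure length %d",
             ids[[i]], nchar(seqs[[i]]), nchar(sss[[i]]))
    ch <- strsplit(sss[[i]], "")[[1]]
    if (!all(ch %in% .STATES))
      .stopf("record '%s': structure contains states outside {H,E,T,C}",
             ids[[i]])
    seqs[[i]] <- .cleanResidues(seqs[[i]])$residues
  }
  data.frame(id = ids, sequence = seqs, structure = sss,
             stringsAsFactors = FALSE)
}

#' Write a paired sequence/structure file
#'
#' @param corpus data frame with columns `id`, `sequence`, `structure`.
#' @param path output file.
#' @export
writePaired <- function(corpus, path) {
  stopifnot(all(c("id", "sequence", "structure") %in% names(corpus)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus)))
    writeLines(c(paste0(">", corpus$id[[i]]), corpus$sequence[[i]],
                 corpus$structure[[i]]), con)
  invisible(path)
}

#' Reduce 8-state DSSP codes to the 4 block types
#'
#' `G`, `H`, `I` (3-10, alpha and pi helices) map to helix; `E` to
#' strand; `T` (hydrogen-bonded turn) to turn; `B` (beta bridge), `S`
#' (bend), `C` and blank to coil.
#'
#' @param codes string over the 8-letter DSSP alphabet (blank/space
#'   allowed).
#' @return 4-state string of the same length.
#' @examples
#' mapDssp8To4("GHIE")  # "HHHE"
#' @export
mapDssp8To4 <- function(codes) {
  if (!nchar(codes)) return("")
  ch <- strsplit(codes, "")[[1]]
  map <- c(G = "H", H = "H", I = "H", E = "E", T = "T",
           B = "C", S = "C", C = "C", " " = "C")
  out <- map[ch]
  if (anyNA(out))
    .stopf("unknown DSSP code(s): %s",
           paste(unique(ch[is.na(out)]), collapse = ", "))
  paste(out, collapse = "")
}

#' Minimal classic DSSP file reader
#'
#' Parses the fixed-column residue section of a classic `.dssp` file
#' (amino acid in column 14, secondary structure in column 17, chain id
#' in column 12), applies the 8 -> 4 state reduction, and returns one
#' paired record per chain. Chain-break markers (`!`) split records.
#'
#' @param path classic-format DSSP file.
#' @return Data frame with columns `id`, `sequence`, `structure`.
#' @export
readDssp <- function(path) {
  lines <- readLines(path)
  start <- grep("^  #  RESIDUE", lines)
  if (!length(start))
    .stopf("'%s' does not look like a classic DSSP file (no residue header)",
           path)
  lines <- lines[(start[[1L]] + 1L):length(lines)]
  ids <- character(); seqs <- character(); sss <- character()
  curChain <- ""; curSeq <- character(); curSS <- character()
  flush <- function() {
    if (length(curSeq)) {
      ids <<- c(ids, curChain)
      seqs <<- c(seqs, paste(curSeq, collapse = ""))
      sss <<- c(sss, mapDssp8To4(paste(curSS, collapse = "")))
    }
    curSeq <<- character(); curSS <<- character()
  }
  for (ln in lines) {
    if (nchar(ln) < 17L) next
    aa <- substr(ln, 14L, 14L)
    if (aa == "!") { flush(); next }
    chain <- substr(ln, 12L, 12L)
    if (nzchar(trimws(chain)) && chain != curChain && length(curSeq)) flush()
    curChain <- chain
    curSeq <- c(curSeq, .cleanResidues(aa)$residues)
    curSS <- c(curSS, substr(ln, 17L, 17L))
  }
  flush()
  if (!length(ids)) .stopf("'%s' contains no residue records", path)
  data.frame(id = ids, sequence = seqs, structure = sss,
             stringsAsFactors = FALSE)
}

#' Build a per-position state count matrix from aligned structures
#'
#' Each aligned homolog contributes its 4-state structure string,
#' gapped (`-`) and aligned to the query columns. Gaps are excluded
#' from the counts, so the per-position depth is the number of
#' sequences minus the gaps in that column.
#'
#' @param alignedStructures character vector of gapped 4-state strings,
#'   each with `queryLength` columns.
#' @param queryLength number of query positions.
#' @param alpha Dirichlet hyperparameters for the resulting profile.
#' @return An [MsaProfile-class].
#' @export
buildMsaProfile <- function(alignedStructures, queryLength, alpha = 1) {
  counts <- matrix(0L, queryLength, 4L, dimnames = list(NULL, .STATES))
  for (s in alignedStructures) {
    if (nchar(s) != queryLength)
      .stopf("aligned structure has %d columns, expected %d", nchar(s),
             queryLength)
    ch <- strsplit(s, "")[[1]]
    keep <- ch != "-"
    if (!all(ch[keep] %in% .STATES))
      .stopf("aligned structure contains states outside {H,E,T,C,-}")
    idx <- which(keep)
    for (l in idx)
      counts[l, ch[[l]]] <- counts[l, ch[[l]]] + 1L
  }
  MsaProfile(counts, alpha = alpha)
}

#' Read / write an MSA count matrix as TSV
#'
#' Columns: `pos` (1-based), `H`, `E`, `T`, `C`.
#'
#' @param path TSV file.
#' @param alpha Dirichlet hyperparameters for the resulting profile.
#' @return [readMsaCounts()] returns an [MsaProfile-class].
#' @export
readMsaCounts <- function(path, alpha = 1) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  need <- c("pos", .STATES)
  if (!all(need %in% names(df)))
    .stopf("MSA count TSV must have columns pos, H, E, T, C")
  df <- df[order(df$pos), ]
  if (!identical(as.integer(df$pos), seq_len(nrow(df))))
    .stopf("MSA count TSV positions must be 1..L without gaps")
  MsaProfile(as.matrix(df[, .STATES]), alpha = alpha)
}

#' @param profile an [MsaProfile-class].
#' @rdname readMsaCounts
#' @export
writeMsaCounts <- function(profile, path) {
  df <- data.frame(pos = seq_len(nrow(profile@counts)), profile@counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a prediction report TSV
#'
#' Columns: `pos` (1-based), `residue`, `state` (the point estimate),
#' and the four marginal probabilities `pH, pE, pT, pC` (each row sums
#' to 1).
#'
#' @param sequence amino-acid sequence.
#' @param prediction predicted state string.
#' @param marginals L x 4 marginal matrix (columns `H,E,T,C`).
#' @param path output file.
#' @export
writePrediction <- function(sequence, prediction, marginals, path) {
  L <- nchar(sequence)
  stopifnot(nchar(prediction) == L, nrow(marginals) == L)
  df <- data.frame(pos = seq_len(L),
                   residue = strsplit(sequence, "")[[1]],
                   state = strsplit(prediction, "")[[1]],
                   pH = marginals[, "H"], pE = marginals[, "E"],
                   pT = marginals[, "T"], pC = marginals[, "C"])
  utils::write.table(format(df, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a prediction report TSV
#'
#' @param path file written by [writePrediction()].
#' @return Data frame with the report columns.
#' @export
readPrediction <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("integer", "character",
                                         "character", rep("numeric", 4L)))
  need <- c("pos", "residue", "state", "pH", "pE", "pT", "pC")
  if (!all(need %in% names(df)))
    .stopf("prediction TSV must have columns %s", paste(need, collapse = ", "))
  df
}

.MODEL_FORMAT <- "BlockSS-model"
.MODEL_VERSION <- 1L

#' Write / read a trained model file
#'
#' The model is serialized in its canonical list form (see
#' [modelAsList()]) inside a versioned container; reading verifies the
#' format tag and version, so a corrupt or incompatible file is refused
#' rather than silently misread. The dependency templates and
#' constraint set used at training time travel with the model.
#'
#' @param model a [SecStructModel-class].
#' @param path model file.
#' @return [readModel()] returns the [SecStructModel-class].
#' @export
writeModel <- function(model, path) {
  stopifnot(is(model, "SecStructModel"))
  saveRDS(modelAsList(model), path)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  x <- tryCatch(readRDS(path),
                error = function(e) .stopf("cannot read model file '%s': %s",
                                           path, conditionMessage(e)))
  if (!is.list(x) || !identical(x$format, .MODEL_FORMAT))
    .stopf("'%s' is not a model file", path)
  if (!identical(as.integer(x$version), .MODEL_VERSION))
    .stopf("model file version %s is not supported (expected %d)",
           x$version, .MODEL_VERSION)
  .modelFromList(x)
}

#' Optional corpus curation filters
#'
#' Dataset-preparation rules applied upstream of training: records are
#' optionally split at runs of unknown residues (the paired-format
#' stand-in for missing density) and chains shorter than `minLength`
#' are dropped. Neither rule is part of the model; defaults mirror
#' common corpus curation (25-residue minimum).
#'
#' @param corpus data frame with columns `id`, `sequence`, `structure`.
#' @param minLength drop chains shorter than this (default 25).
#' @param splitAtUnknown split records at runs of `X` before filtering.
#' @return The filtered data frame.
#' @export
filterCorpus <- function(corpus, minLength = 25L, splitAtUnknown = FALSE) {
  stopifnot(all(c("id", "sequence", "structure") %in% names(corpus)))
  if (splitAtUnknown) {
    ids <- character(); seqs <- character(); sss <- character()
    for (i in seq_len(nrow(corpus))) {
      m <- gregexpr("[^X]+", corpus$sequence[[i]])[[1]]
      pieces <- regmatches(corpus$sequence[[i]], list(m))[[1]]
      for (j in seq_along(pieces)) {
        ids <- c(ids, if (length(pieces) > 1L)
          sprintf("%s_%d", corpus$id[[i]], j) else corpus$id[[i]])
        seqs <- c(seqs, pieces[[j]])
        sss <- c(sss, substr(corpus$structure[[i]], m[[j]],
                             m[[j]] + attr(m, "match.length")[[j]] - 1L))
      }
    }
    corpus <- data.frame(id = ids, sequence = seqs, structure = sss,
                         stringsAsFactors = FALSE)
  }
  keep <- nchar(corpus$sequence) >= minLength
  corpus[keep, , drop = FALSE]
}
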