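# Internal constants and small helpers shared across modules.

# Canonical state order used for every 4-column matrix in the package.
.STATES <- c("H", "E", "T", "C")

# The 20 proteinogenic one-letter codes, plus "X" as the unknown code.
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.UNKNOWN <- "X"

# Environment key for a slot's unconditional (context-free) count table;
# "." cannot collide with an amino-acid context key.
.NOCTX <- "."

.stateIndex <- function(x) {
  i <- match(x, .STATES)
  if (anyNA(i)) stop("unknown secondary-structure state(s): ",
                     paste(unique(x[is.na(i)]), collapse = ", "), call. = FALSE)
  i
}

# Residue string -> integer codes 1..20, 21 for unknown.
.aaCodes <- function(residues) {
  ch <- strsplit(residues, "", fixed = TRUE)[[1]]
  i <- match(ch, .AA20)
  i[is.na(i)] <- 21L
  i
}

.aaIndex <- function(aa) {
  i <- match(aa, .AA20)
  if (is.na(i)) stop("not a standard amino-acid code: ", aa, call. = FALSE)
  i
}

# Map arbitrary residue letters to the standard alphabet; nonstandard -> X.
.cleanResidues <- function(x) {
  x <- toupper(x)
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- !(ch %in% .AA20)
  if (any(bad)) ch[bad] <- .UNKNOWN
  list(residues = paste(ch, collapse = ""), nMapped = sum(bad))
}

.logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
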