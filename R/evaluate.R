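# Prediction scoring: Q3/Q4 accuracy, recall and precision confusion
# matrices (predicted rows x actual columns), and 4 -> 3 state merging
# for comparison with three-state predictors.

#' Merge turn predictions into the coil class
#'
#' Three-state predictors do not model turns separately; for comparison
#' the 4-state string is reduced by `T -> C`, leaving `H` and `E`
#' unchanged.
#'
#' @param linear 4-state string.
#' @return 3-state string over `{H,E,C}`.
#' @examples
#' mergeTurnIntoCoil("CHTEC")  # "CHCEC"
#' @export
mergeTurnIntoCoil <- function(linear) {
  chartr("T", "C", linear)
}

#' Per-residue accuracy (Q3 / Q4)
#'
#' The percentage of positions whose predicted state matches the truth.
#' Called Q4 on 4-state strings and Q3 after [mergeTurnIntoCoil()].
#'
#' @param pred,truth state strings of equal length.
#' @return Accuracy in percent.
#' @export
qAccuracy <- function(pred, truth) {
  if (nchar(pred) != nchar(truth))
    .stopf("prediction length %d != truth length %d", nchar(pred),
           nchar(truth))
  p <- strsplit(pred, "")[[1]]
  t <- strsplit(truth, "")[[1]]
  100 * sum(p == t) / length(t)
}

#' Corpus-level accuracy
#'
#' `micro` pools residues across chains (total matches over total
#' residues); `macro` averages per-chain accuracies. The overall
#' accuracy of a large heterogeneous corpus is conventionally
#' residue-weighted (micro), but both are reported since chain
#' averaging is also in use.
#'
#' @param preds,truths character vectors of per-chain state strings.
#' @param average `"micro"` or `"macro"`.
#' @return Accuracy in percent.
#' @export
qAccuracyCorpus <- function(preds, truths, average = c("micro", "macro")) {
  average <- match.arg(average)
  stopifnot(length(preds) == length(truths))
  if (average == "macro")
    return(mean(mapply(qAccuracy, preds, truths)))
  match_n <- 0L
  total <- 0L
  for (i in seq_along(preds)) {
    p <- strsplit(preds[[i]], "")[[1]]
    t <- strsplit(truths[[i]], "")[[1]]
    if (length(p) != length(t))
      .stopf("chain %d: prediction/truth length mismatch", i)
    match_n <- match_n + sum(p == t)
    total <- total + length(t)
  }
  100 * match_n / total
}

#' Confusion matrix with recall and precision normalizations
#'
#' Counts predicted (rows) against actual (columns) states over one or
#' more aligned chains. The recall matrix normalizes each actual-class
#' column to 100; the precision matrix normalizes each predicted-class
#' row to 100. Classes with no instances render as zero rows/columns
#' and are flagged rather than producing NaN.
#'
#' @param preds,truths character vectors of per-chain state strings.
#' @param classes class labels (default `c("H","E","C")` for merged
#'   3-state scoring; use `c("H","E","T","C")` for 4-state).
#' @return A [ConfusionSummary-class].
#' @export
confusionSummary <- function(preds, truths, classes = c("H", "E", "C")) {
  stopifnot(length(preds) == length(truths))
  p <- unlist(strsplit(preds, ""))
  t <- unlist(strsplit(truths, ""))
  if (length(p) != length(t))
    .stopf("total prediction and truth lengths differ")
  bad <- unique(c(p[!p %in% classes], t[!t %in% classes]))
  if (length(bad))
    .stopf("state labels outside the declared classes: %s",
           paste(bad, collapse = ", "))
  counts <- table(factor(p, levels = classes), factor(t, levels = classes))
  counts <- matrix(as.integer(counts), length(classes), length(classes),
                   dimnames = list(predicted = classes, actual = classes))
  colSum <- colSums(counts)
  rowSum <- rowSums(counts)
  recall <- sweep(counts, 2L, ifelse(colSum > 0, colSum, 1), "/") * 100
  precision <- sweep(counts, 1L, ifelse(rowSum > 0, rowSum, 1), "/") * 100
  new("ConfusionSummary", counts = counts, recall = recall,
      precision = precision,
      emptyActual = classes[colSum == 0],
      emptyPredicted = classes[rowSum == 0])
}
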