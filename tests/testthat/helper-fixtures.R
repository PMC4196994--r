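# Shared fixtures: a synthetic generator spec, a training corpus drawn
# from it, and a toy model trained on that corpus. Built once per test
# run; all sizes are small enough for sub-second reuse.

fixtureSpec <- generatorSpec(seed = 7)

fixtureCorpus <- local({
  set.seed(101)
  simulateCorpus(fixtureSpec, 300, lengthRange = c(20, 40))
})

fixtureModel <- trainModel(fixtureCorpus)

# a random valid annotation of total length L under default constraints
randomValidAnnotation <- function(L) {
  anns <- enumerateValid(L)
  anns[[sample.int(length(anns), 1L)]]
}

# independent aggregation of probabilities over canonical structures
canonicalProbs <- function(keys, probs) {
  can <- vapply(keys, function(k) {
    m <- gregexpr("[HETC][0-9]+", k)[[1]]
    parts <- regmatches(k, list(m))[[1]]
    ann <- BlockAnnotation(substr(parts, 1, 1),
                           as.integer(substring(parts, 2)))
    blocksToLinear(ann)
  }, character(1))
  tapply(probs, can, sum)
}

totalVariation <- function(p, q) {
  keys <- union(names(p), names(q))
  g <- function(v) { x <- v[keys]; x[is.na(x)] <- 0; x }
  0.5 * sum(abs(g(p) - g(q)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
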