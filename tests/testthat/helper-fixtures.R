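# Small graph builders and the registered weight list used across tests.

pathGraph <- function(n) {
  graphFromEdgeList(lapply(seq_len(n - 1L),
    function(i) c(paste0("v", i), paste0("v", i + 1L))))
}

cycleGraph <- function(n) {
  graphFromEdgeList(lapply(seq_len(n),
    function(i) c(paste0("v", i), paste0("v", i %% n + 1L))))
}

starGraph <- function(k) {
  graphFromEdgeList(lapply(seq_len(k), function(i) c("c", paste0("l", i))))
}

# Every registered weight as a concrete spec: the Randic index at its four
# standard exponents plus the other fifteen names (including aliases).
allSpecs <- function(includeBalaban = TRUE) {
  names <- setdiff(weightNames(), "randic")
  if (!includeBalaban) names <- setdiff(names, "balaban")
  c(lapply(c(1, -1, 0.5, -0.5), function(a) weightSpec("randic", a)),
    lapply(names, weightSpec))
}

# Deterministic diverse set of random connected graphs (n <= 30).
randomGraphSet <- function(m, seedBase = 1000L) {
  lapply(seq_len(m), function(i) {
    n <- 2L + (i * 7L) %% 29L            # 2..30
    extra <- min(i %% 4L, n * (n - 1L) / 2L - (n - 1L))
    randomConnectedGraph(n, extraEdges = extra, seed = seedBase + i)
  })
}

# TRUE if the graph's partition contains the (1,1) class on which the
# augmented Zagreb weight is singular.
hasSingularAziClass <- function(part) {
  any(part@pairs[, 1L] == 1L & part@pairs[, 2L] == 1L & part@counts > 0L)
}
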