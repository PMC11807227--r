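# Shannon-type entropies over edge weights and vertex information
# functions. The edge-weight entropy normalizes the per-edge weights F(rs)
# into a probability distribution; classes only make the sum cheaper.

.checkBase <- function(base) {
  if (!is.numeric(base) || length(base) != 1L || !is.finite(base) || base <= 1) {
    .reventStop("bad_record", "logarithm base must be a single number > 1")
  }
  base
}

.entropyFromWeights <- function(weights, counts, base, label, nOutcomes) {
  if (any(!is.finite(weights))) {
    .reventStop("bad_record", "entropy weights must be finite")
  }
  if (any(weights < 0)) {
    .reventStop("negative_weight", "entropy weights must be non-negative")
  }
  total <- sum(counts * weights)
  if (total <= 0) {
    .reventStop("zero_total_weight", "total weight is zero; entropy undefined")
  }
  # log(T) - (1/T) * sum count * F * log F, with 0*log 0 = 0
  lw <- ifelse(weights > 0, log(weights, base = base), 0)
  value <- log(total, base = base) - sum(counts * weights * lw) / total
  new("EntropyResult", value = value, base = base, weight = label,
      totalWeight = total, nOutcomes = as.integer(nOutcomes))
}

#' Edge-weight entropy of a graph or partition
#'
#' The Shannon entropy of the distribution obtained by normalizing the
#' per-edge weights F(rs) by their total: equivalently
#' `log(sum F) - (1/sum F) * sum F log F` over edges, computed per class.
#' The value lies in `[0, log_base(q)]`, with the maximum attained exactly
#' when all per-edge weights are equal. Zero weights (the atom-bond
#' connectivity weight on a (1,1) class) contribute nothing, by the
#' `0 log 0 = 0` convention; the normalizer keeps every edge.
#'
#' @param x an [EdgePartition-class] or [MolecularGraph-class]
#' @param spec a [WeightSpec-class] or weight name.
#' @param base logarithm base (> 1); natural log by default. Changing from
#'   base e to base b divides the value by ln(b), exactly.
#' @return an [EntropyResult-class]
#' @examples
#' c4 <- graphFromEdgeList(list(c("1","2"), c("2","3"), c("3","4"), c("4","1")))
#' entropyValue(edgeWeightEntropy(c4, "m1"))  # log(4): uniform weights
#' @rdname edgeWeightEntropy
#' @export
setMethod("edgeWeightEntropy", "EdgePartition", function(x, spec, base = exp(1)) {
  .checkBase(base)
  spec <- .asWeightSpec(spec)
  keep <- x@counts > 0L
  pr <- x@pairs[keep, , drop = FALSE]
  cnt <- x@counts[keep]
  ctx <- if (spec@needsContext) {
    if (is.na(x@p)) {
      .reventStop("needs_context", "balaban entropy needs the (p, q) context")
    }
    c(x@p, x@q)
  }
  w <- edgeWeight(spec, pr[, 1L], pr[, 2L], context = ctx)
  .entropyFromWeights(w, cnt, base, weightLabel(spec), x@q)
})

#' @rdname edgeWeightEntropy
#' @export
setMethod("edgeWeightEntropy", "MolecularGraph", function(x, spec, base = exp(1)) {
  edgeWeightEntropy(edgePartition(x), spec, base = base)
})

#' Vertex-information entropy
#'
#' Shannon entropy of the distribution obtained by normalizing a positive
#' vertex information function f by its true total:
#' `-sum_i (f_i / sum f) log(f_i / sum f)`. For the reverse-degree
#' information function the normalizer is `sum Upsilon = p(Delta+1) - 2q`
#' (not 2q, which holds for plain degrees only).
#'
#' @param g a [MolecularGraph-class]
#' @param info information function: `"reverse_degree"` (default) or
#'   `"degree"`.
#' @param base logarithm base (> 1).
#' @return an [EntropyResult-class] with `nOutcomes = p`
#' @examples
#' k13 <- graphFromEdgeList(list(c("c","l1"), c("c","l2"), c("c","l3")))
#' entropyValue(vertexInformationEntropy(k13))  # log(10) - 9*log(3)/10
#' @export
vertexInformationEntropy <- function(g, info = c("reverse_degree", "degree"),
                                     base = exp(1)) {
  stopifnot(is(g, "MolecularGraph"))
  .checkBase(base)
  info <- match.arg(info)
  f <- switch(info,
    reverse_degree = as.numeric(upsilon(reverseDegrees(g))),
    degree = as.numeric(degrees(g)))
  if (any(f <= 0)) {
    .reventStop("negative_weight", "vertex information values must be positive")
  }
  .entropyFromWeights(f, rep(1L, length(f)), base, info, numVertices(g))
}

#' Displayed-form class-aggregated entropy (diagnostic)
#'
#' Evaluates `log(T) - (1/T) * sum_classes log(count * F^F)` with T the
#' index value. This aggregation treats each class through
#' `log(count * F^F)` rather than the `count * F * log(F)` that the true
#' edge-weight entropy requires, so it is NOT mathematically equivalent to
#' [edgeWeightEntropy()]; it is provided solely as a diagnostic for
#' comparing against class-aggregated tabulations computed this way.
#' Computed via `log(count) + F*log(F)` so large classes do not overflow.
#'
#' @param partition an [EdgePartition-class]
#' @param spec a [WeightSpec-class] or weight name.
#' @param base logarithm base (> 1).
#' @return numeric scalar
#' @export
displayedFormEntropy <- function(partition, spec, base = exp(1)) {
  stopifnot(is(partition, "EdgePartition"))
  .checkBase(base)
  spec <- .asWeightSpec(spec)
  keep <- partition@counts > 0L
  pr <- partition@pairs[keep, , drop = FALSE]
  cnt <- partition@counts[keep]
  ctx <- if (spec@needsContext) c(partition@p, partition@q)
  w <- edgeWeight(spec, pr[, 1L], pr[, 2L], context = ctx)
  if (any(w < 0)) .reventStop("negative_weight", "weights must be non-negative")
  total <- sum(cnt * w)
  if (total <= 0) .reventStop("zero_total_weight", "total weight is zero")
  lw <- ifelse(w > 0, log(w, base = base), 0)       # F log F with 0^0 = 1
  log(total, base = base) - sum(log(cnt, base = base) + w * lw) / total
}

#' @describeIn entropyValue entropy value of a result
#' @export
setMethod("entropyValue", "EntropyResult", function(x) x@value)

setMethod("show", "EntropyResult", function(object) {
  baseTxt <- if (isTRUE(all.equal(object@base, exp(1)))) "e" else
    format(object@base)
  cat(sprintf(
    "EntropyResult: %.6f (base %s) over %d outcomes [weight %s, total %.6g]\n",
    object@value, baseTxt, object@nOutcomes, object@weight, object@totalWeight))
})
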