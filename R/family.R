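# Parameterized edge-partition families: class counts affine in the
# polymer repeat parameter s, exact affine closed forms for every index,
# and entropy curves over s. Ships the hyaluronic acid-paclitaxel (HA-PTX)
# conjugate partition as the built-in fixture.

#' Construct a parameterized edge partition
#'
#' @param classes data.frame with columns `a`, `b`, `slope`, `intercept`;
#'   the count of a class at repeat level s is `slope*s + intercept`.
#' @param sMin smallest admissible integer s (default 1). Construction
#'   fails if any count would be negative at `sMin` (or for larger s, i.e.
#'   negative slopes are rejected).
#' @return a [ParameterizedPartition-class]
#' @export
parameterizedPartition <- function(classes, sMin = 1L) {
  stopifnot(all(c("a", "b", "slope", "intercept") %in% names(classes)))
  a <- as.integer(pmin(classes$a, classes$b))
  b <- as.integer(pmax(classes$a, classes$b))
  o <- order(a, b)
  new("ParameterizedPartition",
      pairs = cbind(a, b, deparse.level = 0)[o, , drop = FALSE],
      slopes = as.integer(classes$slope)[o],
      intercepts = as.integer(classes$intercept)[o],
      sMin = as.integer(sMin))
}

#' The hyaluronic acid-paclitaxel conjugate edge partition
#'
#' The reverse-degree edge partition of the HA-PTX conjugate with
#' polymerization degree s >= 1: nine classes with affine counts
#' (2,2): s; (2,3): 7s; (3,3): 19s-1; (2,4): 3s; (3,4): 32s-1;
#' (4,4): 13s+1; (2,5): 4s; (3,5): 16s; (4,5): s+1. The total edge count is
#' q(s) = 96s. The same partition ships as
#' `system.file("extdata", "haptx_partition.csv", package = "revent")`.
#'
#' @return a [ParameterizedPartition-class]
#' @examples
#' partitionClasses(evaluateAt(haptxPartition(), 1))
#' @export
haptxPartition <- function() {
  parameterizedPartition(data.frame(
    a         = c(2L, 2L, 3L, 2L, 3L, 4L, 2L, 3L, 4L),
    b         = c(2L, 3L, 3L, 4L, 4L, 4L, 5L, 5L, 5L),
    slope     = c(1L, 7L, 19L, 3L, 32L, 13L, 4L, 16L, 1L),
    intercept = c(0L, 0L, -1L, 0L, -1L, 1L, 0L, 0L, 1L)))
}

#' @describeIn partitionClasses affine classes of a parameterized partition
#' @export
setMethod("partitionClasses", "ParameterizedPartition", function(x) {
  data.frame(a = x@pairs[, 1L], b = x@pairs[, 2L],
             slope = x@slopes, intercept = x@intercepts)
})

setMethod("show", "ParameterizedPartition", function(object) {
  cat(sprintf(
    "ParameterizedPartition: %d classes, q(s) = %ds%+d, s >= %d\n",
    nrow(object@pairs), sum(object@slopes), sum(object@intercepts),
    object@sMin))
  print(partitionClasses(object), row.names = FALSE)
})

#' Evaluate a parameterized partition or affine form at s
#'
#' @param x a [ParameterizedPartition-class] or [AffineForm-class]
#' @param s integer repeat level, `s >= sMin` for partitions.
#' @return for a partition, the concrete [EdgePartition-class] with counts
#'   `slope*s + intercept`; for an affine form, the numeric value
#'   `slope*s + intercept`.
#' @examples
#' numEdges(evaluateAt(haptxPartition(), 2))  # 192
#' @rdname evaluateAt
#' @export
setMethod("evaluateAt", "ParameterizedPartition", function(x, s) {
  s <- as.integer(s)
  stopifnot(length(s) == 1L)
  if (is.na(s) || s < x@sMin) {
    .reventStop("below_smin", sprintf("s = %s is below sMin = %d", s, x@sMin))
  }
  cnt <- x@slopes * s + x@intercepts
  if (any(cnt < 0L)) {
    .reventStop("negative_count", "evaluated class count is negative")
  }
  edgePartitionFromClasses(
    data.frame(a = x@pairs[, 1L], b = x@pairs[, 2L], count = cnt))
})

#' @rdname evaluateAt
#' @export
setMethod("evaluateAt", "AffineForm", function(x, s) x@slope * s + x@intercept)

#' Affine closed form of an index over a parameterized partition
#'
#' Because every index is linear in class counts, its value over the family
#' is exactly `slope*s + intercept` with
#' `slope = sum(class_slope * F(a,b))` and
#' `intercept = sum(class_intercept * F(a,b))`. Context-dependent weights
#' (balaban) are unsupported: a parameterized partition carries no vertex
#' count p(s).
#'
#' @param pp a [ParameterizedPartition-class]
#' @param spec a [WeightSpec-class] or weight name.
#' @param alpha convenience Randic exponent when `spec` is a bare name.
#' @return an [AffineForm-class]
#' @examples
#' affineIndex(haptxPartition(), "m1")   # 664 s + 4
#' affineIndex(haptxPartition(), "abc")  # 62.6009 s - 0.1082
#' @export
affineIndex <- function(pp, spec, alpha = NULL) {
  stopifnot(is(pp, "ParameterizedPartition"))
  spec <- .asWeightSpec(spec, alpha)
  if (spec@needsContext) {
    .reventStop("needs_context",
      "balaban has no affine closed form here: the family carries no p(s)")
  }
  w <- edgeWeight(spec, pp@pairs[, 1L], pp@pairs[, 2L])
  new("AffineForm", slope = sum(pp@slopes * w),
      intercept = sum(pp@intercepts * w))
}

#' @describeIn affineSlope slope of an affine closed form
#' @export
setMethod("affineSlope", "AffineForm", function(x) x@slope)

#' @describeIn affineIntercept intercept of an affine closed form
#' @export
setMethod("affineIntercept", "AffineForm", function(x) x@intercept)

setMethod("show", "AffineForm", function(object) {
  cat(sprintf("AffineForm: %.6g s %s %.6g\n", object@slope,
              if (object@intercept < 0) "-" else "+", abs(object@intercept)))
})

#' Entropy table over a range of repeat levels
#'
#' One row per s, one column per weight; each cell is the edge-weight
#' entropy (or, with `displayed = TRUE`, the class-aggregated diagnostic
#' form) of the partition evaluated at that s.
#'
#' @param pp a [ParameterizedPartition-class]
#' @param specs list of [WeightSpec-class] objects or weight names.
#' @param sValues integer vector of repeat levels, all `>= sMin`.
#' @param base logarithm base (> 1).
#' @param displayed use [displayedFormEntropy()] instead of
#'   [edgeWeightEntropy()].
#' @return data.frame with column `s` then one numeric column per weight
#' @examples
#' entropyTable(haptxPartition(), list("m1", "abc"), 1:3)
#' @export
entropyTable <- function(pp, specs, sValues, base = exp(1), displayed = FALSE) {
  stopifnot(is(pp, "ParameterizedPartition"))
  specs <- lapply(specs, .asWeightSpec)
  labels <- vapply(specs, weightLabel, character(1))
  out <- data.frame(s = as.integer(sValues))
  for (lab in labels) out[[lab]] <- numeric(length(sValues))
  for (i in seq_along(sValues)) {
    part <- evaluateAt(pp, sValues[i])
    for (j in seq_along(specs)) {
      out[i, labels[j]] <- if (displayed) {
        displayedFormEntropy(part, specs[[j]], base = base)
      } else {
        entropyValue(edgeWeightEntropy(part, specs[[j]], base = base))
      }
    }
  }
  out
}
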