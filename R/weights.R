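# Registry of reverse-degree edge-weight functions and index computation.
# Every index here is a sum of F(a, b) over edges, with (a, b) the sorted
# endpoint reverse degrees, so an EdgePartition is a sufficient statistic.

.weightRegistry <- c("randic", "abc", "ga", "m1", "m2", "hm", "forgotten",
                     "azi", "balaban", "rezg1", "rezg2", "rezg3", "mm2",
                     "harmonic", "sdd", "isi")

.defaultAlphas <- c(1, -1, 0.5, -0.5)

#' Names of the registered edge-weight functions
#'
#' `mm2` is the alias randic(alpha = -1); `isi` (inverse-sum-indeg) the
#' alias `rezg2`. `balaban` is the only context-dependent weight (it needs
#' the graph's p and q).
#'
#' @return character vector of weight names
#' @export
weightNames <- function() .weightRegistry

#' Construct a WeightSpec
#'
#' @param name a registered weight name (see [weightNames()]).
#' @param alpha Randic exponent, required iff `name = "randic"`; restricted
#'   to 1, -1, 1/2, -1/2 unless `allowAnyAlpha = TRUE`.
#' @param allowAnyAlpha allow arbitrary real Randic exponents.
#' @return a [WeightSpec-class]
#' @examples
#' weightSpec("abc")
#' weightSpec("randic", alpha = -1/2)
#' @export
weightSpec <- function(name, alpha = NULL, allowAnyAlpha = FALSE) {
  name <- match.arg(tolower(name), .weightRegistry)
  if (name == "randic") {
    if (is.null(alpha)) {
      .reventStop("bad_alpha", "randic weight needs an alpha exponent")
    }
    if (!allowAnyAlpha && !any(abs(alpha - .defaultAlphas) < 1e-12)) {
      .reventStop("bad_alpha",
        "alpha restricted to 1, -1, 1/2, -1/2; use allowAnyAlpha = TRUE to override")
    }
    alpha <- as.numeric(alpha)
  } else if (name == "mm2") {
    alpha <- -1                               # alias randic(-1)
  } else {
    if (!is.null(alpha)) {
      .reventStop("bad_alpha", sprintf("weight '%s' takes no alpha", name))
    }
    alpha <- numeric(0)
  }
  new("WeightSpec", name = name, alpha = alpha,
      needsContext = identical(name, "balaban"))
}

# Accept a WeightSpec or a bare name anywhere a spec is expected.
.asWeightSpec <- function(spec, alpha = NULL) {
  if (is(spec, "WeightSpec")) return(spec)
  weightSpec(spec, alpha = alpha)
}

#' Label used for a weight in tabular output
#'
#' @param spec a [WeightSpec-class] or weight name.
#' @return a single string, e.g. `"abc"` or `"randic_-0.5"`
#' @export
weightLabel <- function(spec) {
  spec <- .asWeightSpec(spec)
  if (spec@name == "randic") sprintf("randic_%g", spec@alpha) else spec@name
}

setMethod("show", "WeightSpec", function(object) {
  cat(sprintf("WeightSpec '%s'%s%s\n", object@name,
              if (length(object@alpha) && object@name == "randic")
                sprintf(" (alpha = %g)", object@alpha) else "",
              if (object@needsContext) " [needs (p, q) context]" else ""))
})

#' Evaluate an edge-weight function on a reverse-degree pair
#'
#' Formulas (a, b are the endpoint reverse degrees):
#' randic `(ab)^alpha`; abc `sqrt((a+b-2)/(ab))` (0 on (1,1) since the
#' numerator vanishes); ga `2*sqrt(ab)/(a+b)`; m1 `a+b`; m2 `ab`;
#' hm `(a+b)^2`; forgotten `a^2+b^2`; azi `(ab/(a+b-2))^3` (domain error on
#' (1,1)); balaban `(q/(q-p+2)) / sqrt(ab)`; rezg1 `(a+b)/(ab)`;
#' rezg2 = isi `ab/(a+b)`; rezg3 `ab(a+b)`; harmonic `2/(a+b)`;
#' sdd `(a^2+b^2)/(ab)`; mm2 = randic(-1) `1/(ab)`.
#'
#' @param spec a [WeightSpec-class] or weight name.
#' @param a,b positive integer reverse degrees (vectorized).
#' @param context numeric `c(p, q)`; required iff the weight is
#'   context-dependent (balaban).
#' @return numeric vector of weights
#' @examples
#' edgeWeight("m1", 3, 4)                       # 7
#' edgeWeight("abc", 3, 4)                      # sqrt(5/12)
#' edgeWeight("balaban", 1, 1, context = c(4, 4))
#' @export
edgeWeight <- function(spec, a, b, context = NULL) {
  spec <- .asWeightSpec(spec)
  stopifnot(length(a) == length(b))
  if (any(a < 1) || any(b < 1)) {
    .reventStop("bad_record", "reverse degrees must be >= 1")
  }
  a <- as.numeric(a); b <- as.numeric(b)
  name <- spec@name
  if (name == "mm2") name <- "randic"          # alias randic(-1)
  if (name == "isi") name <- "rezg2"           # alias
  if (name == "azi" && any(a + b == 2)) {
    .reventStop("azi_singular",
      "augmented Zagreb weight is undefined on a (1,1) class (zero denominator)")
  }
  if (name == "balaban") {
    if (is.null(context) || length(context) != 2L || anyNA(context)) {
      .reventStop("needs_context", "balaban weight needs the (p, q) context")
    }
    p <- context[[1L]]; q <- context[[2L]]
    return(q / (q - p + 2) / sqrt(a * b))
  }
  switch(name,
    randic    = (a * b)^spec@alpha,
    abc       = sqrt((a + b - 2) / (a * b)),
    ga        = 2 * sqrt(a * b) / (a + b),
    m1        = a + b,
    m2        = a * b,
    hm        = (a + b)^2,
    forgotten = a^2 + b^2,
    azi       = (a * b / (a + b - 2))^3,
    rezg1     = (a + b) / (a * b),
    rezg2     = a * b / (a + b),
    rezg3     = a * b * (a + b),
    harmonic  = 2 / (a + b),
    sdd       = (a^2 + b^2) / (a * b))
}

#' Topological index from an edge partition
#'
#' value = sum over classes of count * F(a, b). The context-dependent
#' balaban weight takes (p, q) from the partition.
#'
#' @param partition an [EdgePartition-class]
#' @param spec a [WeightSpec-class] or weight name.
#' @param alpha convenience Randic exponent when `spec` is a bare name.
#' @return the index value, a finite numeric scalar
#' @examples
#' c4 <- graphFromEdgeList(list(c("1","2"), c("2","3"), c("3","4"), c("4","1")))
#' indexFromPartition(edgePartition(c4), "m1")  # 8
#' @export
indexFromPartition <- function(partition, spec, alpha = NULL) {
  stopifnot(is(partition, "EdgePartition"))
  spec <- .asWeightSpec(spec, alpha)
  keep <- partition@counts > 0L
  pr <- partition@pairs[keep, , drop = FALSE]
  cnt <- partition@counts[keep]
  ctx <- if (spec@needsContext) {
    if (is.na(partition@p)) {
      .reventStop("needs_context",
        "balaban index needs a partition with vertex-count context p")
    }
    c(partition@p, partition@q)
  }
  val <- sum(cnt * edgeWeight(spec, pr[, 1L], pr[, 2L], context = ctx))
  if (!is.finite(val)) .reventStop("bad_record", "index value is not finite")
  val
}

#' Topological index of a graph
#'
#' Equal to `indexFromPartition(edgePartition(g), spec)`; the balaban
#' context (p, q) is filled from the graph.
#'
#' @inheritParams indexFromPartition
#' @param g a [MolecularGraph-class]
#' @return the index value
#' @export
indexFromGraph <- function(g, spec, alpha = NULL) {
  indexFromPartition(edgePartition(g), spec, alpha = alpha)
}

#' All registered indices of a graph
#'
#' Evaluates every registered weight: the Randic index at the four standard
#' exponents plus the twelve other weights and the aliases. Per-weight
#' domain failures (the augmented Zagreb (1,1) singularity) are reported as
#' `undefined` rows instead of aborting the batch.
#'
#' @param g a [MolecularGraph-class]
#' @return data.frame with columns `weight`, `value`, `status`, `reason`
#' @export
allIndices <- function(g) {
  stopifnot(is(g, "MolecularGraph"))
  part <- edgePartition(g)
  specs <- c(lapply(.defaultAlphas, function(al) weightSpec("randic", al)),
             lapply(setdiff(.weightRegistry, "randic"), weightSpec))
  rows <- lapply(specs, function(sp) {
    val <- tryCatch(indexFromPartition(part, sp),
                    revent_error = function(e) e)
    if (inherits(val, "condition")) {
      data.frame(weight = weightLabel(sp), value = NA_real_,
                 status = "undefined", reason = conditionMessage(val))
    } else {
      data.frame(weight = weightLabel(sp), value = val,
                 status = "ok", reason = "")
    }
  })
  do.call(rbind, rows)
}

#' Brute-force per-edge index (independent oracle)
#'
#' Loops over raw edges and recomputes every reverse degree from scratch,
#' bypassing [edgePartition()] entirely. Intended for tests, where it serves
#' as the independent check on the partition-based computation.
#'
#' @inheritParams indexFromGraph
#' @return the index value
#' @export
bruteForceIndex <- function(g, spec, alpha = NULL) {
  stopifnot(is(g, "MolecularGraph"))
  spec <- .asWeightSpec(spec, alpha)
  ed <- edgeMatrix(g)
  labs <- vertexLabels(g)
  d <- vapply(labs, function(v) sum(ed == v), integer(1))
  D <- max(d)
  ups <- D - d + 1L
  ctx <- if (spec@needsContext) c(length(labs), nrow(ed))
  total <- 0
  for (i in seq_len(nrow(ed))) {
    total <- total + edgeWeight(spec, ups[[ed[i, 1L]]], ups[[ed[i, 2L]]],
                                context = ctx)
  }
  total
}
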