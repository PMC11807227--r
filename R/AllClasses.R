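#' @import methods
NULL

#' MolecularGraph: a simple connected hydrogen-suppressed molecular graph
#'
#' Vertices are opaque atom labels, edges are chemical bonds. The class
#' enforces the model used throughout the package: a finite, simple,
#' connected, undirected graph with at least one edge. Bond orders and
#' charges are not represented; an aromatic or double bond contributes a
#' single edge.
#'
#' @slot vertices character vector of vertex labels, sorted.
#' @slot edges two-column character matrix; each row is an unordered bond,
#'   stored with the lexicographically smaller label first and rows in
#'   canonical order, so all outputs are independent of insertion order.
#'
#' @seealso [molecularGraph()], [graphFromEdgeList()], [graphFromAdjacency()],
#'   [graphFromSmiles()], [randomConnectedGraph()]
#' @export
setClass("MolecularGraph",
  slots = c(vertices = "character", edges = "matrix"))

setValidity("MolecularGraph", function(object) {
  ed <- object@edges
  v <- object@vertices
  if (!is.character(ed) || ncol(ed) != 2L) {
    return("edges must be a two-column character matrix")
  }
  if (length(v) < 2L) return("a molecular graph needs at least two atoms (p >= 2)")
  if (nrow(ed) < 1L) return("a molecular graph needs at least one bond (q >= 1)")
  if (any(ed[, 1L] == ed[, 2L])) return("self-loops are not allowed")
  key <- paste(ed[, 1L], ed[, 2L], sep = "\r")
  if (anyDuplicated(key)) return("duplicate edges are not allowed")
  if (!all(as.vector(ed) %in% v)) return("edge endpoints must be declared vertices")
  if (!.isConnected(v, ed)) return("graph must be connected")
  TRUE
})

#' ReverseDegreeProfile: per-vertex reverse degrees
#'
#' For a graph with maximum degree Delta, the reverse degree of vertex v is
#' Upsilon(v) = Delta - d(v) + 1, always >= 1, with the minimum value 1
#' attained at every maximum-degree vertex. Delta is always the maximum
#' degree of the input graph itself, never an external constant.
#'
#' @slot maxDegree the maximum degree Delta of the graph.
#' @slot upsilon named integer vector of reverse degrees, one per vertex.
#' @seealso [reverseDegrees()]
#' @export
setClass("ReverseDegreeProfile",
  slots = c(maxDegree = "integer", upsilon = "integer"))

setValidity("ReverseDegreeProfile", function(object) {
  if (length(object@maxDegree) != 1L || object@maxDegree < 1L) {
    return("maxDegree must be a single positive integer")
  }
  if (any(object@upsilon < 1L)) return("reverse degrees must be >= 1")
  if (min(object@upsilon) != 1L) {
    return("some vertex must attain reverse degree 1 (a maximum-degree vertex)")
  }
  TRUE
})

#' EdgePartition: edge classes keyed by sorted reverse-degree pairs
#'
#' The multiset of (a, b) reverse-degree pairs with multiplicities. It is a
#' sufficient statistic for every index and entropy in this package: each
#' edge contributes to exactly one class and the counts sum to q.
#'
#' @slot pairs two-column integer matrix of distinct (a, b) pairs, a <= b,
#'   in canonical (a, b) order.
#' @slot counts non-negative integer count per class; sum equals `q`.
#' @slot p vertex count of the originating graph (`NA` if unknown, e.g. for
#'   a partition read from a file without context).
#' @slot q edge count; always the sum of `counts`.
#' @seealso [edgePartition()], [edgePartitionFromClasses()]
#' @export
setClass("EdgePartition",
  slots = c(pairs = "matrix", counts = "integer", p = "integer", q = "integer"))

setValidity("EdgePartition", function(object) {
  pr <- object@pairs
  if (!is.integer(pr) || ncol(pr) != 2L) {
    return("pairs must be a two-column integer matrix")
  }
  if (nrow(pr) != length(object@counts)) return("one count per class required")
  if (nrow(pr) > 0L) {
    if (any(pr < 1L)) return("reverse degrees in pairs must be >= 1")
    if (any(pr[, 1L] > pr[, 2L])) return("pairs must be sorted, a <= b")
    if (anyDuplicated(paste(pr[, 1L], pr[, 2L]))) return("pairs must be distinct")
  }
  if (any(object@counts < 0L)) return("class counts must be non-negative")
  if (sum(object@counts) != object@q) return("class counts must sum to q")
  TRUE
})

#' WeightSpec: a named reverse-degree edge-weight function
#'
#' Identifies one of the registered edge-weight functions F(a, b) used for
#' both indices and entropies. `randic` carries an exponent alpha; `balaban`
#' additionally needs the graph context (p, q) for its q/(q - p + 2)
#' prefactor. `mm2` is the alias randic(alpha = -1) and `isi` the alias
#' `rezg2`; aliases evaluate identically.
#'
#' @slot name registered weight name.
#' @slot alpha Randic exponent (length 0 unless name is "randic"/"mm2").
#' @slot needsContext TRUE only for "balaban".
#' @seealso [weightSpec()], [edgeWeight()], [weightNames()]
#' @export
setClass("WeightSpec",
  slots = c(name = "character", alpha = "numeric", needsContext = "logical"))

#' EntropyResult: a Shannon-type graph entropy value with its metadata
#'
#' @slot value the entropy, in units of the logarithm base.
#' @slot base logarithm base (> 1); natural log by default.
#' @slot weight label of the edge-weight function or vertex information
#'   function the entropy was taken over.
#' @slot totalWeight the normalizer (sum of all weights).
#' @slot nOutcomes number of outcomes: q for edge entropies, p for vertex
#'   entropies. The entropy lies in [0, log_base(nOutcomes)].
#' @seealso [edgeWeightEntropy()], [vertexInformationEntropy()]
#' @export
setClass("EntropyResult",
  slots = c(value = "numeric", base = "numeric", weight = "character",
            totalWeight = "numeric", nOutcomes = "integer"))

#' ParameterizedPartition: edge classes with counts affine in a repeat unit s
#'
#' Models polymer-like families where the count of class i at repeat level s
#' is slope_i * s + intercept_i. Validated so that every count is
#' non-negative for all integer s >= sMin.
#'
#' @slot pairs two-column integer matrix of distinct sorted (a, b) pairs.
#' @slot slopes,intercepts integer affine coefficients per class.
#' @slot sMin smallest admissible s (default 1).
#' @seealso [parameterizedPartition()], [haptxPartition()], [evaluateAt()],
#'   [affineIndex()]
#' @export
setClass("ParameterizedPartition",
  slots = c(pairs = "matrix", slopes = "integer", intercepts = "integer",
            sMin = "integer"))

setValidity("ParameterizedPartition", function(object) {
  pr <- object@pairs
  if (!is.integer(pr) || ncol(pr) != 2L) {
    return("pairs must be a two-column integer matrix")
  }
  if (nrow(pr) != length(object@slopes) || nrow(pr) != length(object@intercepts)) {
    return("slopes and intercepts must have one entry per class")
  }
  if (nrow(pr) > 0L) {
    if (any(pr < 1L)) return("reverse degrees in pairs must be >= 1")
    if (any(pr[, 1L] > pr[, 2L])) return("pairs must be sorted, a <= b")
    if (anyDuplicated(paste(pr[, 1L], pr[, 2L]))) return("pairs must be distinct")
  }
  if (any(object@slopes < 0L)) {
    return("a negative slope gives negative counts for large s")
  }
  if (any(object@slopes * object@sMin + object@intercepts < 0L)) {
    return("class counts must be non-negative at s = sMin")
  }
  TRUE
})

#' AffineForm: an index closed form slope * s + intercept
#'
#' Every reverse-degree index is linear in edge-class counts, so over a
#' [ParameterizedPartition] it is exactly affine in s.
#'
#' @slot slope,intercept real affine coefficients.
#' @seealso [affineIndex()], [evaluateAt()]
#' @export
setClass("AffineForm", slots = c(slope = "numeric", intercept = "numeric"))

#' QsprFit: a fitted descriptor-to-property regression model
#'
#' Linear-family fits (ols, ridge, lasso, enet) store coefficients on the
#' original descriptor scale together with the standardization metadata used
#' internally; support-vector fits keep the underlying model object.
#'
#' @slot method one of "ols", "ridge", "lasso", "enet", "svr".
#' @slot coefficients named numeric vector on the original descriptor scale
#'   (length 0 for svr).
#' @slot intercept model intercept (NA for svr).
#' @slot hyper list of hyperparameters used.
#' @slot center,scale standardization means and scales of the descriptors
#'   used internally by the penalized fits ("scale" of 1 and center of 0 for
#'   unstandardized ols).
#' @slot featureNames descriptor names in model order.
#' @slot model underlying fitted object where one exists (e1071 svm), else NULL.
#' @seealso [qsprFit()], [fitMetrics()], [equationText()]
#' @export
setClass("QsprFit",
  slots = c(method = "character", coefficients = "numeric",
            intercept = "numeric", hyper = "list", center = "numeric",
            scale = "numeric", featureNames = "character", model = "ANY"))
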