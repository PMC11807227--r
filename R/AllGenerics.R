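#' @rdname reverseDegrees
#' @export
setGeneric("reverseDegrees", function(x) standardGeneric("reverseDegrees"))

#' @rdname edgePartition
#' @export
setGeneric("edgePartition", function(x) standardGeneric("edgePartition"))

#' @rdname edgeWeightEntropy
#' @export
setGeneric("edgeWeightEntropy",
  function(x, spec, base = exp(1)) standardGeneric("edgeWeightEntropy"))

#' @rdname evaluateAt
#' @export
setGeneric("evaluateAt", function(x, s) standardGeneric("evaluateAt"))

#' Number of vertices (atoms)
#' @param x a [MolecularGraph-class]
#' @return integer vertex count p
#' @export
setGeneric("numVertices", function(x) standardGeneric("numVertices"))

#' Number of edges (bonds)
#' @param x a [MolecularGraph-class] or [EdgePartition-class]
#' @return integer edge count q
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' Vertex labels
#' @param x a [MolecularGraph-class]
#' @return character vector of labels, sorted
#' @export
setGeneric("vertexLabels", function(x) standardGeneric("vertexLabels"))

#' Edge matrix
#' @param x a [MolecularGraph-class]
#' @return two-column character matrix of bonds in canonical order
#' @export
setGeneric("edgeMatrix", function(x) standardGeneric("edgeMatrix"))

#' Maximum degree
#' @param x a [ReverseDegreeProfile-class]
#' @return the maximum degree Delta of the profiled graph
#' @export
setGeneric("maxDegree", function(x) standardGeneric("maxDegree"))

#' Reverse degrees
#' @param x a [ReverseDegreeProfile-class]
#' @return named integer vector Upsilon(v) per vertex
#' @export
setGeneric("upsilon", function(x) standardGeneric("upsilon"))

#' Edge classes of a partition as a data.frame
#' @param x an [EdgePartition-class] or [ParameterizedPartition-class]
#' @return for a concrete partition, columns `a`, `b`, `count`; for a
#'   parameterized one, columns `a`, `b`, `slope`, `intercept`
#' @export
setGeneric("partitionClasses", function(x) standardGeneric("partitionClasses"))

#' Entropy value
#' @param x an [EntropyResult-class]
#' @return the numeric entropy, in units of the stored logarithm base
#' @export
setGeneric("entropyValue", function(x) standardGeneric("entropyValue"))

#' Affine slope
#' @param x an [AffineForm-class]
#' @return numeric slope of the closed form
#' @export
setGeneric("affineSlope", function(x) standardGeneric("affineSlope"))

#' Affine intercept
#' @param x an [AffineForm-class]
#' @return numeric intercept of the closed form
#' @export
setGeneric("affineIntercept", function(x) standardGeneric("affineIntercept"))
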