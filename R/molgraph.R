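# Graph data model: constructors, accessors, reverse degrees, edge partition,
# and the synthetic generator used by the property tests.

.isConnected <- function(vertices, edges) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1L], to = edges[, 2L]),
    directed = FALSE, vertices = data.frame(name = vertices))
  igraph::count_components(g) == 1L
}

.canonicalEdges <- function(edges) {
  swap <- edges[, 1L] > edges[, 2L]
  if (any(swap)) edges[swap, ] <- edges[swap, c(2L, 1L), drop = FALSE]
  edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
}

#' Construct a molecular graph from bonds
#'
#' @param edges a two-column character matrix or data.frame of bonds; each
#'   row is one edge as an unordered pair of vertex labels.
#' @param vertices optional vector of vertex labels; defaults to the union
#'   of the edge endpoints. Extra labels beyond the endpoints make the graph
#'   disconnected and are rejected.
#' @return a validated [MolecularGraph-class]
#' @examples
#' g <- molecularGraph(rbind(c("a", "b"), c("b", "c")))
#' numVertices(g); numEdges(g)
#' @export
molecularGraph <- function(edges, vertices = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.null(edges) || length(edges) == 0L || nrow(edges) == 0L) {
    .reventStop("empty_input", "no edges supplied: a molecular graph needs at least one bond")
  }
  if (ncol(edges) != 2L) {
    .reventStop("bad_record", "each edge record must have exactly two vertex labels")
  }
  mode(edges) <- "character"
  if (anyNA(edges) || any(!nzchar(edges))) {
    .reventStop("bad_record", "edge records must not contain missing or empty labels")
  }
  if (any(edges[, 1L] == edges[, 2L])) {
    bad <- edges[edges[, 1L] == edges[, 2L], 1L][1L]
    .reventStop("self_loop", sprintf("self-loop on vertex '%s' is not allowed", bad))
  }
  edges <- .canonicalEdges(unname(edges))
  key <- paste(edges[, 1L], edges[, 2L], sep = "\r")
  if (anyDuplicated(key)) {
    dup <- edges[duplicated(key), , drop = FALSE][1L, ]
    .reventStop("duplicate_edge",
      sprintf("duplicate edge between '%s' and '%s'", dup[1L], dup[2L]))
  }
  if (is.null(vertices)) vertices <- unique(as.vector(edges))
  vertices <- sort(as.character(vertices))
  if (!all(as.vector(edges) %in% vertices)) {
    .reventStop("bad_record", "edges refer to labels missing from 'vertices'")
  }
  if (!.isConnected(vertices, edges)) {
    .reventStop("disconnected", "graph is disconnected; analyze fragments separately")
  }
  new("MolecularGraph", vertices = vertices, edges = edges)
}

#' Build a graph from edge-list records
#'
#' Accepts the records of a whitespace edge-list file: one bond per record,
#' two labels each.
#'
#' @param records a two-column matrix/data.frame, or a list of length-2
#'   character vectors.
#' @return a [MolecularGraph-class]
#' @examples
#' graphFromEdgeList(list(c("a", "b"), c("b", "c")))
#' @export
graphFromEdgeList <- function(records) {
  if (is.list(records) && !is.data.frame(records)) {
    if (length(records) == 0L) {
      .reventStop("empty_input", "empty edge list")
    }
    if (any(lengths(records) != 2L)) {
      .reventStop("bad_record", "each edge record must have exactly two vertex labels")
    }
    records <- do.call(rbind, lapply(records, as.character))
  }
  molecularGraph(records)
}

#' Build a graph from a 0/1 adjacency matrix
#'
#' @param m square numeric matrix with entries in {0, 1}, symmetric, zero
#'   diagonal.
#' @param labels optional vertex labels; defaults to the dimnames of `m` or
#'   `v1..vn`.
#' @return a [MolecularGraph-class] whose edges are the upper-triangle ones.
#' @examples
#' graphFromAdjacency(matrix(c(0, 1, 1, 0), 2))
#' @export
graphFromAdjacency <- function(m, labels = NULL) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) {
    .reventStop("non_symmetric", "adjacency matrix must be square")
  }
  if (!all(m %in% c(0, 1))) {
    .reventStop("non_binary", "adjacency entries must be 0 or 1")
  }
  if (any(diag(m) != 0)) {
    .reventStop("nonzero_diagonal", "adjacency diagonal must be zero (no self-loops)")
  }
  if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE))) {
    .reventStop("non_symmetric", "adjacency matrix must be symmetric")
  }
  if (is.null(labels)) {
    labels <- rownames(m)
    if (is.null(labels)) labels <- colnames(m)
    if (is.null(labels)) labels <- paste0("v", seq_len(nrow(m)))
  }
  if (length(labels) != nrow(m) || anyDuplicated(labels)) {
    .reventStop("bad_labels", "labels must be unique and match the matrix dimension")
  }
  idx <- which(upper.tri(m) & m == 1, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    .reventStop("empty_input", "adjacency matrix has no edges")
  }
  molecularGraph(cbind(labels[idx[, 1L]], labels[idx[, 2L]]), vertices = labels)
}

#' @describeIn numVertices vertex count of a graph
#' @export
setMethod("numVertices", "MolecularGraph", function(x) length(x@vertices))

#' @describeIn numEdges edge count of a graph
#' @export
setMethod("numEdges", "MolecularGraph", function(x) nrow(x@edges))

#' @describeIn vertexLabels labels of a graph
#' @export
setMethod("vertexLabels", "MolecularGraph", function(x) x@vertices)

#' @describeIn edgeMatrix canonical bond matrix of a graph
#' @export
setMethod("edgeMatrix", "MolecularGraph", function(x) x@edges)

setMethod("show", "MolecularGraph", function(object) {
  cat(sprintf("MolecularGraph: p = %d atoms, q = %d bonds\n",
              numVertices(object), numEdges(object)))
  d <- degrees(object)
  cat(sprintf("  max degree %d; degree range [%d, %d]\n",
              max(d), min(d), max(d)))
})

#' Vertex degrees
#'
#' @param g a [MolecularGraph-class]
#' @return named integer vector of degrees d(v), in label order
#' @export
degrees <- function(g) {
  stopifnot(is(g, "MolecularGraph"))
  d <- table(factor(as.vector(g@edges), levels = g@vertices))
  stats::setNames(as.integer(d), g@vertices)
}

#' Reverse degrees of a graph
#'
#' Computes Upsilon(v) = Delta - d(v) + 1 for every vertex, where Delta is
#' the maximum degree of `x` itself. Note that embedding a graph in a larger
#' one changes Delta and therefore every reverse degree.
#'
#' @param x a [MolecularGraph-class]
#' @return a [ReverseDegreeProfile-class]
#' @examples
#' p3 <- graphFromEdgeList(list(c("a", "b"), c("b", "c")))
#' upsilon(reverseDegrees(p3)) # ends 2, middle 1
#' @rdname reverseDegrees
#' @export
setMethod("reverseDegrees", "MolecularGraph", function(x) {
  d <- degrees(x)
  D <- max(d)
  new("ReverseDegreeProfile", maxDegree = as.integer(D),
      upsilon = stats::setNames(as.integer(D - d + 1L), names(d)))
})

#' @describeIn maxDegree maximum degree stored in a profile
#' @export
setMethod("maxDegree", "ReverseDegreeProfile", function(x) x@maxDegree)

#' @describeIn upsilon reverse degrees stored in a profile
#' @export
setMethod("upsilon", "ReverseDegreeProfile", function(x) x@upsilon)

setMethod("show", "ReverseDegreeProfile", function(object) {
  cat(sprintf("ReverseDegreeProfile: Delta = %d, %d vertices\n",
              object@maxDegree, length(object@upsilon)))
  print(table(object@upsilon))
})

#' Construct an edge partition from explicit classes
#'
#' @param classes data.frame with columns `a`, `b`, `count` (one row per
#'   reverse-degree class); unsorted pairs are sorted, repeated pairs merged.
#' @param p optional vertex count context (needed only for the Balaban-type
#'   weight).
#' @return an [EdgePartition-class]
#' @export
edgePartitionFromClasses <- function(classes, p = NA_integer_) {
  stopifnot(all(c("a", "b", "count") %in% names(classes)))
  a <- as.integer(pmin(classes$a, classes$b))
  b <- as.integer(pmax(classes$a, classes$b))
  cnt <- as.integer(classes$count)
  if (any(cnt < 0L)) .reventStop("negative_count", "class counts must be non-negative")
  key <- paste(a, b)
  if (anyDuplicated(key)) {
    cnt <- as.integer(tapply(cnt, key, sum)[unique(key)])
    keep <- !duplicated(key)
    a <- a[keep]; b <- b[keep]
  }
  o <- order(a, b)
  new("EdgePartition", pairs = cbind(a, b, deparse.level = 0)[o, , drop = FALSE],
      counts = cnt[o], p = as.integer(p), q = sum(cnt))
}

#' Edge partition of a graph by reverse-degree pairs
#'
#' Each edge contributes to exactly one class keyed by the sorted pair of
#' endpoint reverse degrees; counts sum to q and the (p, q) context is
#' recorded for context-dependent weights.
#'
#' @param x a [MolecularGraph-class]
#' @return an [EdgePartition-class]
#' @examples
#' c4 <- graphFromEdgeList(list(c("1","2"), c("2","3"), c("3","4"), c("4","1")))
#' partitionClasses(edgePartition(c4)) # single class (1,1) with count 4
#' @rdname edgePartition
#' @export
setMethod("edgePartition", "MolecularGraph", function(x) {
  ups <- upsilon(reverseDegrees(x))
  ea <- ups[x@edges[, 1L]]
  eb <- ups[x@edges[, 2L]]
  df <- data.frame(a = pmin(ea, eb), b = pmax(ea, eb), count = 1L)
  agg <- stats::aggregate(count ~ a + b, data = df, FUN = sum)
  edgePartitionFromClasses(agg, p = numVertices(x))
})

#' @describeIn partitionClasses classes of a concrete partition
#' @export
setMethod("partitionClasses", "EdgePartition", function(x) {
  data.frame(a = x@pairs[, 1L], b = x@pairs[, 2L], count = x@counts)
})

#' @describeIn numEdges total edge count of a partition
#' @export
setMethod("numEdges", "EdgePartition", function(x) x@q)

setMethod("show", "EdgePartition", function(object) {
  cat(sprintf("EdgePartition: %d classes, q = %d edges%s\n",
              nrow(object@pairs), object@q,
              if (is.na(object@p)) "" else sprintf(", p = %d", object@p)))
  print(partitionClasses(object), row.names = FALSE)
})

.withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Random connected graph generator
#'
#' Draws a uniform random labeled spanning tree on n vertices (via a random
#' Pruefer sequence) and adds `extraEdges` distinct non-tree edges chosen
#' uniformly at random. Deterministic for a fixed seed, and always a valid
#' [MolecularGraph-class]. This is the synthetic generator behind the
#' package's property tests; it emulates connectivity and cycle content of
#' molecular graphs, not chemistry (no valence constraints).
#'
#' @param n number of vertices (>= 2).
#' @param extraEdges number of non-tree edges to add (>= 0).
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return a [MolecularGraph-class] with q = n - 1 + extraEdges
#' @examples
#' numEdges(randomConnectedGraph(6, extraEdges = 3, seed = 42)) # 8
#' @export
randomConnectedGraph <- function(n, extraEdges = 0L, seed) {
  n <- as.integer(n)
  extraEdges <- as.integer(extraEdges)
  if (n < 2L) .reventStop("bad_record", "n must be at least 2")
  if (extraEdges < 0L) .reventStop("bad_record", "extraEdges must be >= 0")
  maxExtra <- n * (n - 1L) / 2L - (n - 1L)
  if (extraEdges > maxExtra) {
    .reventStop("too_many_edges",
      sprintf("extraEdges = %d exceeds the %d available non-tree pairs", extraEdges, maxExtra))
  }
  .withSeed(seed, {
    if (n == 2L) {
      tree <- matrix(c(1L, 2L), 1L)
    } else {
      pruefer <- sample.int(n, n - 2L, replace = TRUE)
      deg <- tabulate(pruefer, n) + 1L
      tree <- matrix(0L, n - 1L, 2L)
      for (i in seq_len(n - 2L)) {
        leaf <- which.max(deg == 1L)          # smallest-index leaf
        tree[i, ] <- c(leaf, pruefer[i])
        deg[leaf] <- 0L
        deg[pruefer[i]] <- deg[pruefer[i]] - 1L
      }
      tree[n - 1L, ] <- which(deg == 1L)
    }
    edges <- t(apply(tree, 1L, sort))
    if (extraEdges > 0L) {
      all <- which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
      key <- paste(all[, 1L], all[, 2L])
      used <- paste(edges[, 1L], edges[, 2L])
      free <- which(!(key %in% used))
      pick <- free[sample.int(length(free), extraEdges)]
      edges <- rbind(edges, all[pick, , drop = FALSE])
    }
    width <- nchar(as.character(n))
    lab <- sprintf(paste0("v%0", width, "d"), seq_len(n))
    molecularGraph(cbind(lab[edges[, 1L]], lab[edges[, 2L]]))
  })
}
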