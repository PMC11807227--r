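# File formats: whitespace edge lists ('#' comments), CSV adjacency matrices
# (optional label header/first column), and partition CSVs.

.checkFile <- function(path) {
  if (!file.exists(path)) {
    .reventStop("file_not_found", sprintf("file not found: %s", path))
  }
  path
}

#' Read a molecular graph from a whitespace edge-list file
#'
#' UTF-8 text, one edge per line, two whitespace-separated labels; blank
#' lines and `#` comments are ignored.
#'
#' @param path file path.
#' @return a [MolecularGraph-class]
#' @export
readEdgeList <- function(path) {
  lines <- readLines(.checkFile(path), encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    .reventStop("empty_input", sprintf("no edges in %s", path))
  }
  toks <- strsplit(lines, "[[:space:]]+")
  if (any(lengths(toks) != 2L)) {
    bad <- which(lengths(toks) != 2L)[1L]
    .reventStop("bad_record",
      sprintf("edge record %d does not have exactly two labels: '%s'", bad, lines[bad]))
  }
  graphFromEdgeList(toks)
}

#' Write a graph as an edge list
#'
#' Round-trips with [readEdgeList()]: re-reading reproduces the same labeled
#' graph.
#'
#' @param g a [MolecularGraph-class]
#' @param path output file path.
#' @return `path`, invisibly
#' @export
writeEdgeList <- function(g, path) {
  stopifnot(is(g, "MolecularGraph"))
  ed <- edgeMatrix(g)
  writeLines(paste(ed[, 1L], ed[, 2L]), path, useBytes = TRUE)
  invisible(path)
}

#' Adjacency matrix of a graph
#'
#' @param g a [MolecularGraph-class]
#' @return symmetric 0/1 integer matrix with label dimnames;
#'   [graphFromAdjacency()] applied to it returns the identical labeled graph.
#' @export
adjacencyMatrix <- function(g) {
  stopifnot(is(g, "MolecularGraph"))
  v <- vertexLabels(g)
  m <- matrix(0L, length(v), length(v), dimnames = list(v, v))
  ed <- edgeMatrix(g)
  m[cbind(ed[, 1L], ed[, 2L])] <- 1L
  m[cbind(ed[, 2L], ed[, 1L])] <- 1L
  m
}

#' Read an adjacency matrix CSV
#'
#' CSV with optional label header row and/or label first column; body 0/1.
#'
#' @param path file path.
#' @return a [MolecularGraph-class]
#' @export
readAdjacency <- function(path) {
  raw <- utils::read.csv(.checkFile(path), header = FALSE, comment.char = "#",
                         colClasses = "character")
  labels <- NULL
  numericRow <- function(v) !anyNA(suppressWarnings(as.numeric(v)))
  # header row: any non-numeric cell beyond a possibly empty corner
  if (!numericRow(unlist(raw[1L, -1L])) || !nzchar(raw[1L, 1L])) {
    labels <- as.character(unlist(raw[1L, ]))
    raw <- raw[-1L, , drop = FALSE]
  }
  # a leading label column shows up as one extra column on a square body
  if (ncol(raw) == nrow(raw) + 1L) {
    colLabels <- as.character(raw[[1L]])
    raw <- raw[, -1L, drop = FALSE]
    labels <- if (is.null(labels)) colLabels else labels[-1L]
  }
  m <- as.matrix(raw)
  mode(m) <- "numeric"
  if (anyNA(m)) .reventStop("non_binary", "adjacency entries must be 0 or 1")
  graphFromAdjacency(m, labels = labels)
}

#' Write an adjacency matrix CSV
#'
#' @param g a [MolecularGraph-class]
#' @param path output file path.
#' @return `path`, invisibly
#' @export
writeAdjacency <- function(g, path) {
  m <- adjacencyMatrix(g)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' Read a concrete edge partition from CSV
#'
#' Header `a,b,count`, integer cells, `#` comments allowed.
#'
#' @param path file path.
#' @param p optional vertex-count context.
#' @return an [EdgePartition-class]
#' @export
readPartition <- function(path, p = NA_integer_) {
  df <- utils::read.csv(.checkFile(path), comment.char = "#")
  if (!all(c("a", "b", "count") %in% names(df))) {
    .reventStop("bad_record", "partition CSV needs columns a,b,count")
  }
  edgePartitionFromClasses(df, p = p)
}

#' Read a parameterized edge partition from CSV
#'
#' Header `a,b,slope,intercept`, integer cells, `#` comments allowed; class
#' counts at repeat level s are slope*s + intercept.
#'
#' @param path file path.
#' @param sMin smallest admissible s (default 1).
#' @return a [ParameterizedPartition-class]
#' @export
readParameterizedPartition <- function(path, sMin = 1L) {
  df <- utils::read.csv(.checkFile(path), comment.char = "#")
  if (!all(c("a", "b", "slope", "intercept") %in% names(df))) {
    .reventStop("bad_record", "partition CSV needs columns a,b,slope,intercept")
  }
  parameterizedPartition(df, sMin = sMin)
}
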