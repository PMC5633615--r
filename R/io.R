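# File formats. TSV is the canonical dialect (tab separator, '.' decimal,
# UTF-8, '#' comments); CSV is accepted on read. Adjacency files carry node
# labels in the first row and column; edge lists are 3-column
# (node_i, node_j, weight). Partitions are 2-column TSV or a JSON mapping.

.stopValidation <- function(...) {
  stop(structure(class = c("netaggrValidationError", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

.readTableFile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) .stopValidation("empty file: ", path)
  sep <- if (any(grepl("\t", lines))) "\t" else ","
  list(fields = strsplit(lines, sep, fixed = TRUE), sep = sep)
}

#' Read a network from adjacency or edge-list plus partition files
#'
#' Adjacency files have node labels in the first row (leading cell empty)
#' and first column with a dense numeric body; edge lists have three
#' columns (node_i, node_j, weight) with an optional header. The format is
#' auto-detected: a first line starting with the separator (or with more
#' than three fields) is an adjacency header; exactly three fields with a
#' non-empty first cell is an edge list. Pass \code{format} explicitly for
#' ambiguous 3-column adjacency files. The partition file is 2-column TSV
#' (node_label, area_id) or a JSON object mapping labels to area ids.
#'
#' @param adjacencyPath path to the adjacency/edge-list file.
#' @param partitionPath path to the partition file.
#' @param format "auto", "adjacency" or "edgelist".
#' @return a \linkS4class{ConnectivityNetwork}.
#' @export
readNetwork <- function(adjacencyPath, partitionPath,
                        format = c("auto", "adjacency", "edgelist")) {
  format <- match.arg(format)
  tab <- .readTableFile(adjacencyPath)
  fields <- tab$fields
  if (format == "auto") {
    f1 <- fields[[1]]
    format <- if (length(f1) == 3 && nzchar(trimws(f1[1])) &&
                  is.na(suppressWarnings(as.numeric(f1[2]))))
      "edgelist"
    else if (length(f1) == 3 && nzchar(trimws(f1[1])))
      "edgelist"
    else "adjacency"
  }
  if (format == "adjacency") {
    header <- trimws(fields[[1]])
    labels <- header[nzchar(header)]
    N <- length(labels)
    body <- fields[-1]
    if (length(body) != N)
      .stopValidation("adjacency body has ", length(body),
                      " rows for ", N, " labelled columns")
    K <- matrix(NA_real_, N, N)
    rowLabels <- character(N)
    for (i in seq_len(N)) {
      f <- trimws(body[[i]])
      if (length(f) != N + 1)
        .stopValidation("adjacency row ", i, " has ", length(f),
                        " fields, expected ", N + 1)
      rowLabels[i] <- f[1]
      vals <- suppressWarnings(as.numeric(f[-1]))
      if (any(is.na(vals)))
        .stopValidation("non-numeric cell in adjacency row ", i,
                        " (", rowLabels[i], ")")
      K[i, ] <- vals
    }
    if (!identical(rowLabels, labels))
      .stopValidation("adjacency row labels disagree with column labels")
  } else {
    rows <- fields
    first <- trimws(rows[[1]])
    if (is.na(suppressWarnings(as.numeric(first[3])))) rows <- rows[-1]
    ij <- lapply(rows, function(f) {
      f <- trimws(f)
      if (length(f) != 3)
        .stopValidation("edge-list rows need 3 fields (node_i, node_j, ",
                        "weight)")
      w <- suppressWarnings(as.numeric(f[3]))
      if (is.na(w)) .stopValidation("non-numeric weight '", f[3], "'")
      list(i = f[1], j = f[2], w = w)
    })
    labels <- sort(unique(unlist(lapply(ij, function(e) c(e$i, e$j)))))
    N <- length(labels)
    W <- matrix(0, N, N, dimnames = list(labels, labels))
    for (e in ij) {
      W[e$i, e$j] <- e$w
      W[e$j, e$i] <- e$w
    }
    K <- W - diag(rowSums(W))
    rowLabels <- labels
  }
  part <- readPartitionFile(partitionPath)
  missing <- setdiff(rowLabels, names(part))
  if (length(missing))
    .stopValidation("partition missing label(s): ",
                    paste(missing, collapse = ", "))
  unknown <- setdiff(names(part), rowLabels)
  if (length(unknown))
    .stopValidation("partition references unknown label(s): ",
                    paste(unknown, collapse = ", "))
  assignment <- part[rowLabels]
  if (max(abs(K - t(K))) > 1e-9)
    .stopValidation("adjacency matrix is not symmetric ",
                    "(largest asymmetry at row/col ",
                    paste(which(abs(K - t(K)) ==
                                max(abs(K - t(K))), arr.ind = TRUE)[1, ],
                          collapse = "/"), ")")
  connectivityNetwork(K, assignment, nodeLabels = rowLabels)
}

#' Read a partition file
#'
#' @param path 2-column TSV/CSV (node_label, area_id; optional header) or
#'   a JSON object mapping labels to integer area ids.
#' @return named integer vector, label to area.
#' @export
readPartitionFile <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    m <- jsonlite::read_json(path, simplifyVector = TRUE)
    out <- as.integer(unlist(m))
    names(out) <- names(m)
    return(out)
  }
  tab <- .readTableFile(path)
  rows <- tab$fields
  first <- trimws(rows[[1]])
  if (is.na(suppressWarnings(as.integer(first[2])))) rows <- rows[-1]
  labels <- vapply(rows, function(f) trimws(f[1]), character(1))
  areas <- vapply(rows, function(f) {
    a <- suppressWarnings(as.integer(trimws(f[2])))
    if (is.na(a)) .stopValidation("non-integer area id for label '",
                                  trimws(f[1]), "'")
    a
  }, integer(1))
  stats::setNames(areas, labels)
}

#' Write a network to adjacency and partition TSV files
#'
#' Canonical TSV: tab-separated, '.' decimal, labels on the first row
#' (leading empty cell) and column. Writing then reading reproduces the
#' network exactly.
#'
#' @param network a \linkS4class{ConnectivityNetwork}.
#' @param adjacencyPath output adjacency TSV path.
#' @param partitionPath output partition TSV path.
#' @return invisible list of the two paths.
#' @export
writeNetwork <- function(network, adjacencyPath, partitionPath) {
  K <- connMatrix(network)
  labels <- nodeLabels(network)
  lines <- c(paste(c("", labels), collapse = "\t"),
             vapply(seq_len(nrow(K)), function(i)
               paste(c(labels[i],
                       format(K[i, ], digits = 17, trim = TRUE,
                              scientific = FALSE)),
                     collapse = "\t"), character(1)))
  writeLines(lines, adjacencyPath)
  writeLines(c("node_label\tarea_id",
               paste(labels, areaAssignment(network), sep = "\t")),
             partitionPath)
  invisible(list(adjacency = adjacencyPath, partition = partitionPath))
}

#' Read heterogeneous dynamics from JSON
#'
#' Schema: \code{\{n, nodes: [\{label, A\}], coupling: matrix-or-path,
#' gamma: matrix or "lipschitz:<K>", c, f: \{name, gain\}\}}. \code{A} may
#' be a scalar (n = 1) or a row-major matrix; \code{coupling} may inline
#' the matrix or point to a TSV file; \code{"lipschitz:K"} expands Gamma
#' to \eqn{K I_n}.
#'
#' @param path JSON file path.
#' @return list with \code{net} (a \linkS4class{HeterogeneousNetwork}),
#'   \code{c} and \code{labels}.
#' @export
readDynamics <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- if (!is.null(spec$n)) as.integer(spec$n) else 1L
  nodes <- spec$nodes
  AList <- if (is.data.frame(nodes)) lapply(nodes$A, function(A)
    matrix(as.numeric(unlist(A)), n, n, byrow = TRUE))
  else lapply(nodes, function(nd)
    matrix(as.numeric(unlist(nd$A)), n, n, byrow = TRUE))
  labels <- if (is.data.frame(nodes)) nodes$label
  else vapply(nodes, function(nd)
    as.character(nd$label %||% ""), character(1))
  coupling <- spec$coupling
  Dt <- if (is.character(coupling) && length(coupling) == 1) {
    tab <- .readTableFile(coupling)
    do.call(rbind, lapply(tab$fields, function(f) as.numeric(trimws(f))))
  } else matrix(as.numeric(unlist(coupling)), length(AList),
                length(AList), byrow = TRUE)
  gamma <- spec$gamma
  Gamma <- if (is.character(gamma) && grepl("^lipschitz:", gamma))
    as.numeric(sub("^lipschitz:", "", gamma)) * diag(n)
  else matrix(as.numeric(unlist(gamma)), n, n, byrow = TRUE)
  fName <- spec$f$name %||% "tanh"
  fGain <- as.numeric(spec$f$gain %||% 1)
  list(net = heterogeneousNetwork(AList, Dt, Gamma, fName, fGain),
       c = as.numeric(spec$c %||% 1), labels = labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a JSON report
#'
#' @param report named list.
#' @param path output path; when NULL the JSON string is returned.
#' @return path or JSON string, invisibly.
#' @export
writeReport <- function(report, path = NULL) {
  js <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(js, path)
  invisible(path)
}
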