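#' @import methods
NULL

#' Number of nodes
#'
#' @param x an object holding a network.
#' @return integer node count.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' Number of areas
#'
#' @param x an object holding an area partition.
#' @return integer area count \eqn{r}.
#' @export
setGeneric("nAreas", function(x) standardGeneric("nAreas"))

#' Area sizes
#'
#' @param x an object holding an area partition.
#' @return integer vector \eqn{m_\alpha}, one entry per area.
#' @export
setGeneric("areaSizes", function(x) standardGeneric("areaSizes"))

#' Node-to-area assignment
#'
#' @param x an object holding an area partition.
#' @return integer vector mapping each node index to its area index.
#' @export
setGeneric("areaAssignment", function(x) standardGeneric("areaAssignment"))

#' Connection matrix
#'
#' @param x a \linkS4class{ConnectivityNetwork}.
#' @return the total \eqn{N \times N} connection matrix \eqn{K}.
#' @export
setGeneric("connMatrix", function(x) standardGeneric("connMatrix"))

#' Node labels
#'
#' @param x an object carrying labelled nodes.
#' @return character vector of node labels.
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' Area partition accessor
#'
#' @param x a \linkS4class{ConnectivityNetwork}.
#' @return the \linkS4class{AreaPartition}.
#' @export
setGeneric("partition", function(x) standardGeneric("partition"))

#' Incidence matrix accessor
#'
#' @param x an \linkS4class{IncidenceDecomposition}.
#' @return the oriented \eqn{N \times M} incidence matrix \eqn{D}.
#' @export
setGeneric("incidenceMatrix", function(x) standardGeneric("incidenceMatrix"))

#' Pinned node set
#'
#' @param x a \linkS4class{PinningPlan}.
#' @return integer indices of nodes with positive pinning gain.
#' @export
setGeneric("pinnedSet", function(x) standardGeneric("pinnedSet"))

#' Pinning gains
#'
#' @param x a \linkS4class{PinningPlan}.
#' @return numeric vector of per-node gains \eqn{d_i}.
#' @export
setGeneric("gains", function(x) standardGeneric("gains"))

#' Trajectory time grid
#'
#' @param x a \linkS4class{Trajectory}.
#' @return numeric vector of output times.
#' @export
setGeneric("trajTimes", function(x) standardGeneric("trajTimes"))

#' Trajectory states
#'
#' @param x a \linkS4class{Trajectory}.
#' @return numeric matrix, one row per output time.
#' @export
setGeneric("trajStates", function(x) standardGeneric("trajStates"))
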