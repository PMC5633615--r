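# Incidence decomposition, internal/external splitting and the combinatorial
# sparsity parameters. Links are combinatorial: any nonzero off-diagonal
# K_ij defines one undirected link regardless of its weight.

# upper-triangle link table: one row per undirected link {i, j}, i < j
.linkTable <- function(K, assignment) {
  N <- nrow(K)
  idx <- which(upper.tri(K) & K != 0, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(pos = integer(), neg = integer(), area = integer()))
  i <- idx[, 1]; j <- idx[, 2]
  area <- ifelse(assignment[i] == assignment[j], assignment[i], NA_integer_)
  data.frame(pos = i, neg = j, area = as.integer(area))
}

#' Build the oriented incidence decomposition of a clustered network
#'
#' Every nonzero off-diagonal entry of the connection matrix defines one
#' undirected link; diagonal entries are never links. Columns are ordered
#' internal-first (grouped by area, lexicographic by endpoints within each
#' group) then external (lexicographic), so that the internal part is block
#' diagonal over areas. For link \eqn{\{i, j\}} with \eqn{i < j}, node
#' \eqn{i} is the positive end (+1) and \eqn{j} the negative end (-1);
#' linear dynamics are invariant to this orientation choice.
#'
#' @param network a \linkS4class{ConnectivityNetwork}.
#' @return an \linkS4class{IncidenceDecomposition}.
#' @examples
#' inc <- buildIncidence(example1Network())
#' inc@MInternal  # 11 internal links
#' @export
buildIncidence <- function(network) {
  stopifnot(is(network, "ConnectivityNetwork"))
  N <- nNodes(network)
  links <- .linkTable(connMatrix(network), areaAssignment(network))
  internal <- links[!is.na(links$area), , drop = FALSE]
  internal <- internal[order(internal$area, internal$pos, internal$neg), ,
                       drop = FALSE]
  external <- links[is.na(links$area), , drop = FALSE]
  external <- external[order(external$pos, external$neg), , drop = FALSE]
  links <- rbind(internal, external)
  rownames(links) <- NULL
  M <- nrow(links)
  D <- matrix(0L, N, M)
  if (M > 0) {
    D[cbind(links$pos, seq_len(M))] <- 1L
    D[cbind(links$neg, seq_len(M))] <- -1L
  }
  new("IncidenceDecomposition", D = D, MInternal = nrow(internal),
      MExternal = nrow(external), links = links)
}

#' Split the connection matrix into internal and external parts
#'
#' Off-diagonal entries go to the internal part when both endpoints share
#' an area and to the external part otherwise. The diagonal is split so
#' that each internal area block has zero row sums (the internal part is a
#' block-diagonal negative Laplacian); the remainder of the diagonal goes
#' to the external part. The split always reconstructs:
#' \code{KI + KE == K} entrywise. If the external part then fails to have
#' zero row sums (within 1e-9), no Laplacian + Laplacian split exists and
#' an error is raised.
#'
#' @param network a \linkS4class{ConnectivityNetwork}.
#' @return list with matrices \code{KI} and \code{KE}.
#' @examples
#' sp <- splitConnectionMatrix(example1Network())
#' max(abs(sp$KI + sp$KE - connMatrix(example1Network())))
#' @export
splitConnectionMatrix <- function(network) {
  stopifnot(is(network, "ConnectivityNetwork"))
  K <- connMatrix(network)
  assignment <- areaAssignment(network)
  sameArea <- outer(assignment, assignment, "==")
  KI <- K * sameArea
  diag(KI) <- 0
  diag(KI) <- -rowSums(KI)          # internal blocks zero-row-sum
  KE <- K - KI
  if (network@conservative && max(abs(rowSums(KE))) > 1e-9)
    stop("connection matrix is not an internal+external Laplacian sum")
  list(KI = KI, KE = KE)
}

# per-node internal/external link counts (combinatorial)
.linkCounts <- function(network) {
  K <- connMatrix(network)
  assignment <- areaAssignment(network)
  adj <- K != 0
  diag(adj) <- FALSE
  sameArea <- outer(assignment, assignment, "==")
  list(internal = rowSums(adj & sameArea),
       external = rowSums(adj & !sameArea))
}

#' Node sparsity parameter d
#'
#' The ratio \eqn{d = c^E / c^I} of the largest per-node external link
#' count \eqn{c^E} to the smallest per-node internal link count \eqn{c^I}
#' (mode \code{"max_ratio"}). Mode \code{"average"} instead returns the
#' mean over nodes of each node's own external/internal count ratio.
#' Weighted links count as single links; \eqn{d \ll 1} indicates a sparse
#' inter-area structure.
#'
#' @param network a \linkS4class{ConnectivityNetwork}.
#' @param mode "max_ratio" (default) or "average".
#' @return nonnegative scalar.
#' @examples
#' nodeParameter(example1Network())        # 0.5
#' @export
nodeParameter <- function(network, mode = c("max_ratio", "average")) {
  mode <- match.arg(mode)
  cnt <- .linkCounts(network)
  if (any(cnt$internal == 0)) {
    bad <- which(cnt$internal == 0)[1]
    stop("node ", nodeLabels(network)[bad], " (index ", bad, ", area ",
         areaAssignment(network)[bad], ") has zero internal links")
  }
  if (mode == "max_ratio") max(cnt$external) / min(cnt$internal)
  else mean(cnt$external / cnt$internal)
}

# per-area external link counts: each external link counts once for each
# area it touches
.areaExternalCounts <- function(network) {
  links <- .linkTable(connMatrix(network), areaAssignment(network))
  ext <- links[is.na(links$area), , drop = FALSE]
  assignment <- areaAssignment(network)
  r <- nAreas(network)
  counts <- integer(r)
  for (k in seq_len(nrow(ext))) {
    a <- assignment[ext$pos[k]]; b <- assignment[ext$neg[k]]
    counts[a] <- counts[a] + 1L
    counts[b] <- counts[b] + 1L
  }
  counts
}

#' Area sparsity parameter delta
#'
#' \eqn{\delta = \gamma^E / (m c^I)} where \eqn{\gamma^E} is the largest
#' per-area external link count, \eqn{m} the smallest area size and
#' \eqn{c^I} the smallest per-node internal link count.
#'
#' @param network a \linkS4class{ConnectivityNetwork}.
#' @return nonnegative scalar.
#' @examples
#' areaParameter(example1Network())        # 0.25
#' @export
areaParameter <- function(network) {
  cnt <- .linkCounts(network)
  if (any(cnt$internal == 0)) {
    bad <- which(cnt$internal == 0)[1]
    stop("node ", nodeLabels(network)[bad], " (index ", bad, ", area ",
         areaAssignment(network)[bad], ") has zero internal links")
  }
  gammaE <- max(.areaExternalCounts(network), 0L)
  m <- min(areaSizes(network))
  gammaE / (m * min(cnt$internal))
}

#' Combinatorial sparsity summary
#'
#' Collects the raw counts behind the node and area parameters: the
#' minimum internal degree \eqn{c^I}, maximum external degree \eqn{c^E},
#' maximum per-area external link count \eqn{\gamma^E}, minimum area size
#' \eqn{m}, and the derived \eqn{d}, \eqn{d_{ave}} and \eqn{\delta}.
#'
#' @param network a \linkS4class{ConnectivityNetwork}.
#' @return named list of counts and parameters.
#' @export
sparsitySummary <- function(network) {
  cnt <- .linkCounts(network)
  list(cI = min(cnt$internal), cE = max(cnt$external),
       gammaE = max(.areaExternalCounts(network), 0L),
       m = min(areaSizes(network)),
       d = nodeParameter(network, "max_ratio"),
       d_ave = nodeParameter(network, "average"),
       delta = areaParameter(network))
}
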