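# Independent oracles kept deliberately naive: plain loops and direct
# formula evaluation, no reuse of the package's internals.

# brute-force per-node internal/external link counts
oracleLinkCounts <- function(K, assignment) {
  N <- nrow(K)
  internal <- external <- integer(N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j || K[i, j] == 0) next
    if (assignment[i] == assignment[j]) internal[i] <- internal[i] + 1L
    else external[i] <- external[i] + 1L
  }
  list(internal = internal, external = external)
}

# brute-force per-area external link counts (each undirected link once per
# touched area)
oracleAreaExternal <- function(K, assignment) {
  r <- max(assignment)
  counts <- integer(r)
  for (i in seq_len(nrow(K))) for (j in seq_len(ncol(K))) {
    if (i >= j || K[i, j] == 0) next
    if (assignment[i] != assignment[j]) {
      counts[assignment[i]] <- counts[assignment[i]] + 1L
      counts[assignment[j]] <- counts[assignment[j]] + 1L
    }
  }
  counts
}

# unweighted graph Laplacian from an adjacency pattern
oracleLaplacian <- function(adj) diag(rowSums(adj)) - adj

# decoupled per-node pinning criterion, written out directly from its
# scalar/matrix definition
oracleNodeMargin <- function(AList, Dt, Gamma, i, di, c) {
  n <- nrow(as.matrix(AList[[i]]))
  N <- length(AList)
  M <- (as.matrix(AList[[i]]) + t(as.matrix(AList[[i]]))) / 2 -
    di * diag(n) + Dt[i, i] * Gamma
  for (j in seq_len(N)) if (j != i)
    M <- M + abs(Dt[i, j]) / (2 * c) * Gamma %*% t(Gamma)
  for (j in seq_len(N)) if (j != i)
    M <- M + abs(Dt[j, i]) / (2 * c) * diag(n)
  max(eigen((M + t(M)) / 2, symmetric = TRUE)$values)
}

# negative definiteness via Cholesky of the negated symmetrization
oracleNegDefChol <- function(M) {
  S <- -(M + t(M)) / 2
  !inherits(try(chol(S), silent = TRUE), "try-error")
}

# scale the external part of a network's connection matrix by eps
scaleExternal <- function(network, eps) {
  sp <- splitConnectionMatrix(network)
  connectivityNetwork(sp$KI + eps * sp$KE, areaAssignment(network),
                      nodeLabels = nodeLabels(network))
}
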