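# Seeded generators for clustered networks and heterogeneous node dynamics,
# plus the two small worked fixtures used throughout the documentation.

#' Generate a clustered sparse network
#'
#' Builds a network of \code{r} densely connected areas with sparse
#' inter-area links, emulating the topology class the two-time-scale
#' reduction targets. Each area's internal graph is a random spanning tree
#' (guaranteeing connectivity, hence a nonsingular internal Laplacian
#' block and a Hurwitz fast subsystem) plus extra edges until every node
#' reaches the internal minimum degree. External links are then placed
#' between uniformly chosen area pairs subject to per-node and per-area
#' caps, so the emitted network's node parameter is at most
#' \code{externalPerNodeMax / internalMinDegree} and its area parameter at
#' most \code{externalPerAreaMax / (min(sizes) * internalMinDegree)}. The
#' connection matrix is the negative Laplacian of the weighted graph
#' (symmetric, zero row sums). Deterministic under a fixed seed.
#'
#' @param r number of areas.
#' @param sizes integer vector of area sizes (each at least 2).
#' @param internalMinDegree target minimum internal degree \eqn{c^I}.
#' @param externalPerNodeMax cap on external links per node \eqn{c^E}.
#' @param externalPerAreaMax cap on external links per area \eqn{\gamma^E}.
#' @param nExternal number of external links to place (default
#'   \code{externalPerAreaMax}, i.e. the cap of one area).
#' @param weightRange NULL for unit weights, else c(lo, hi) for uniform
#'   draws.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @return a \linkS4class{ConnectivityNetwork}.
#' @examples
#' net <- generateClusteredNetwork(2, c(4, 4), seed = 0)
#' nodeParameter(net) <= 0.5
#' @export
generateClusteredNetwork <- function(r, sizes,
                                     internalMinDegree = 2,
                                     externalPerNodeMax = 1,
                                     externalPerAreaMax = 2,
                                     nExternal = externalPerAreaMax,
                                     weightRange = NULL, seed = 0) {
  sizes <- as.integer(sizes)
  stopifnot(length(sizes) == r, all(sizes >= 2))
  if (any(internalMinDegree > sizes - 1))
    stop("unachievable config: internalMinDegree exceeds area size - 1 ",
         "for area ", which(internalMinDegree > sizes - 1)[1])
  if (r >= 2 && 2 * nExternal > r * externalPerAreaMax)
    stop("unachievable config: requested ", nExternal, " external links ",
         "but per-area cap ", externalPerAreaMax, " over ", r,
         " areas admits at most ", floor(r * externalPerAreaMax / 2))
  N <- sum(sizes)
  offsets <- cumsum(c(0, sizes[-r]))
  withr::with_seed(seed, {
    adj <- matrix(FALSE, N, N)
    for (a in seq_len(r)) {
      nodes <- offsets[a] + seq_len(sizes[a])
      perm <- sample(nodes)
      for (k in 2:length(perm)) {           # random spanning tree
        j <- perm[k]
        i <- perm[sample.int(k - 1, 1)]
        adj[i, j] <- adj[j, i] <- TRUE
      }
      repeat {
        deg <- rowSums(adj[nodes, nodes, drop = FALSE])
        low <- nodes[deg < internalMinDegree]
        if (!length(low)) break
        i <- low[1]
        cand <- setdiff(nodes[!adj[i, nodes]], i)
        if (!length(cand)) break
        j <- if (length(cand) == 1) cand else sample(cand, 1)
        adj[i, j] <- adj[j, i] <- TRUE
      }
    }
    if (r >= 2 && nExternal > 0) {
      assignment <- rep(seq_len(r), sizes)
      nodeExt <- integer(N)
      areaExt <- integer(r)
      placed <- 0
      guard <- 0
      while (placed < nExternal && guard < 10000) {
        guard <- guard + 1
        ab <- sample.int(r, 2)
        iC <- which(assignment == ab[1] & nodeExt < externalPerNodeMax)
        jC <- which(assignment == ab[2] & nodeExt < externalPerNodeMax)
        if (areaExt[ab[1]] >= externalPerAreaMax ||
            areaExt[ab[2]] >= externalPerAreaMax ||
            !length(iC) || !length(jC)) next
        i <- if (length(iC) == 1) iC else sample(iC, 1)
        j <- if (length(jC) == 1) jC else sample(jC, 1)
        if (adj[i, j]) next
        adj[i, j] <- adj[j, i] <- TRUE
        nodeExt[i] <- nodeExt[i] + 1L; nodeExt[j] <- nodeExt[j] + 1L
        areaExt[ab] <- areaExt[ab] + 1L
        placed <- placed + 1
      }
      if (placed < nExternal)
        stop("unachievable config: could only place ", placed, " of ",
             nExternal, " external links under the per-node cap ",
             externalPerNodeMax, " and per-area cap ", externalPerAreaMax)
    }
    W <- matrix(0, N, N)
    up <- which(upper.tri(adj) & adj, arr.ind = TRUE)
    w <- if (is.null(weightRange)) rep(1, nrow(up))
         else stats::runif(nrow(up), weightRange[1], weightRange[2])
    W[up] <- w
    W <- W + t(W)
    K <- W - diag(rowSums(W))
    connectivityNetwork(K, rep(seq_len(r), sizes))
  })
}

#' The 8-node, 2-area worked network
#'
#' The small clustered network used throughout the documentation: two
#' areas of four nodes, internal connection blocks
#' \deqn{K_1^I = \begin{pmatrix} -3&1&1&1\\ 1&-2&1&0\\ 1&1&-3&1\\
#'  1&0&1&-2\end{pmatrix}, \quad K_2^I : \text{complete graph on 4 nodes},}
#' and two external links \{3, 8\} and \{4, 5\} with the matching external
#' diagonal. Its sparsity parameters are \eqn{d = 0.5},
#' \eqn{\delta = 0.25}; the reduced slow matrix has entries
#' \eqn{\pm 0.7634} and slow eigenvalues \{0, -1.5267\}.
#'
#' @return a \linkS4class{ConnectivityNetwork}.
#' @examples
#' nodeParameter(example1Network())   # 0.5
#' @export
example1Network <- function() {
  K1I <- matrix(c(-3, 1, 1, 1,
                  1, -2, 1, 0,
                  1, 1, -3, 1,
                  1, 0, 1, -2), 4, 4, byrow = TRUE)
  K2I <- matrix(1, 4, 4) - 4 * diag(4)
  K12E <- matrix(0, 4, 4)
  K12E[3, 4] <- 1          # link {3, 8}
  K12E[4, 1] <- 1          # link {4, 5}
  K11E <- diag(c(0, 0, -1, -1))
  K22E <- diag(c(-1, 0, 0, -1))
  K <- rbind(cbind(K1I + K11E, K12E),
             cbind(t(K12E), K2I + K22E))
  connectivityNetwork(K, rep(1:2, each = 4))
}

#' The 3-node heterogeneous pinning fixture
#'
#' Three scalar nodes with self-decay magnitudes \eqn{a = (2, 1.6, 0.5)}
#' (state matrices \eqn{A_i = -a_i}), symmetric coupling matrix
#' \deqn{\tilde D = \begin{pmatrix} 0.7 & -0.2 & -0.1 \\
#'   -0.2 & 0.5 & -0.3 \\ -0.1 & -0.3 & 0.8 \end{pmatrix},}
#' sigmoid output \eqn{\bar f = \tanh} with unit gain and Lipschitz bound
#' \eqn{\Gamma = 1}. With \eqn{c = 1} and zero gains the decoupled
#' condition holds at nodes 1 and 2 and fails at node 3, which therefore
#' must be pinned; the minimal gain there is 0.7.
#'
#' @return a \linkS4class{HeterogeneousNetwork}.
#' @examples
#' findPinnedNodes(example3Network(), c = 1)   # 3
#' @export
example3Network <- function() {
  Dt <- matrix(c(0.7, -0.2, -0.1,
                 -0.2, 0.5, -0.3,
                 -0.1, -0.3, 0.8), 3, 3, byrow = TRUE)
  heterogeneousNetwork(list(-2, -1.6, -0.5), Dt, Gamma = 1,
                       fName = "tanh", fGain = 1)
}

#' Generate heterogeneous node dynamics with sparse coupling
#'
#' Draws per-node state matrices \eqn{A_i = -\mathrm{diag}(a)} with decay
#' magnitudes uniform in \code{decayRange} plus a small random skew part
#' (so the \eqn{A_i} are stable but not symmetric), and a sparse symmetric
#' coupling matrix with positive self terms and negative off-diagonal
#' couplings drawn at the requested density. Deterministic under a fixed
#' seed.
#'
#' @param N number of nodes.
#' @param n per-node state dimension.
#' @param decayRange positive interval for the decay magnitudes.
#' @param couplingDensity probability that a node pair is coupled.
#' @param seed integer seed.
#' @return a \linkS4class{HeterogeneousNetwork}.
#' @export
generateHeterogeneousDynamics <- function(N, n = 1, decayRange = c(1, 2),
                                          couplingDensity = 0.2,
                                          seed = 0) {
  stopifnot(all(decayRange > 0))
  withr::with_seed(seed, {
    AList <- lapply(seq_len(N), function(i) {
      S <- matrix(stats::rnorm(n * n, sd = 0.05), n, n)
      -diag(stats::runif(n, decayRange[1], decayRange[2]), nrow = n) +
        (S - t(S))
    })
    Dt <- matrix(0, N, N)
    if (couplingDensity > 0 && N > 1) {
      up <- which(upper.tri(Dt), arr.ind = TRUE)
      on <- stats::runif(nrow(up)) < couplingDensity
      w <- -stats::runif(nrow(up), 0.1, 0.4) * on
      Dt[up] <- w
      Dt <- Dt + t(Dt)
      diag(Dt) <- stats::runif(N, 0.3, 1.0)
    }
    heterogeneousNetwork(AList, Dt, Gamma = 1, fName = "tanh", fGain = 1)
  })
}
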