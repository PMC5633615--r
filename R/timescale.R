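# Slow/fast coordinate transform, singularly perturbed block form, and the
# reduced slow / fast / rigid aggregate models with their spectra.

#' Orthonormal difference matrix
#'
#' The \eqn{(n-1) \times n} within-group difference matrix with orthonormal
#' rows and null vector \eqn{1_n}: first column entries
#' \eqn{-1 + (n-1)\upsilon}, remaining block \eqn{1-\upsilon} on the
#' diagonal and \eqn{-\upsilon} off it, with
#' \eqn{\upsilon = (n - \sqrt n) / (n (n-1))}. Because the rows are
#' orthonormal the pseudoinverse is simply the transpose.
#'
#' @param n group size, integer >= 2.
#' @return \eqn{(n-1) \times n} numeric matrix.
#' @examples
#' orthonormalDifferenceMatrix(2)   # (-1, 1) / sqrt(2)
#' @export
orthonormalDifferenceMatrix <- function(n) {
  if (n < 2) stop("n must be >= 2")
  v <- (n - sqrt(n)) / (n * (n - 1))
  Q <- matrix(-v, n - 1, n)
  Q[, 1] <- -1 + (n - 1) * v
  block <- matrix(-v, n - 1, n - 1)
  diag(block) <- 1 - v
  Q[, -1] <- block
  Q
}

#' Plain difference matrix
#'
#' The non-orthonormal \eqn{(n-1) \times n} dialect with rows
#' \eqn{(-1, 0, ..., 1, ..., 0)}; its pseudoinverse
#' \eqn{Q^+ = Q^T (Q Q^T)^{-1}} replaces the transpose wherever the
#' orthonormal dialect uses \eqn{Q^T}.
#'
#' @param n group size, integer >= 2.
#' @return \eqn{(n-1) \times n} numeric matrix.
#' @export
differenceMatrix <- function(n) {
  if (n < 2) stop("n must be >= 2")
  cbind(rep(-1, n - 1), diag(n - 1))
}

# block diagonal of a list of matrices (possibly with 0-row blocks)
.blockDiag <- function(blocks) {
  nr <- vapply(blocks, nrow, integer(1))
  nc <- vapply(blocks, ncol, integer(1))
  out <- matrix(0, sum(nr), sum(nc))
  r0 <- c0 <- 0
  for (b in blocks) {
    if (nrow(b) > 0)
      out[r0 + seq_len(nrow(b)), c0 + seq_len(ncol(b))] <- b
    r0 <- r0 + nrow(b); c0 <- c0 + ncol(b)
  }
  out
}

#' Build the slow/fast coordinate transform
#'
#' Constructs the aggregate indicator \eqn{U}, the size matrix \eqn{M_a},
#' the averaging matrix \eqn{G = M_a^{-1} U^T}, the block-diagonal fast
#' difference matrix \eqn{Q}, the inter-area difference matrix \eqn{R} and
#' \eqn{C = R M_a^{-1} R^T}. The stacked map \eqn{x \mapsto (y, z)} with
#' \eqn{y = G x}, \eqn{z = Q x} is invertible with inverse
#' \eqn{[U | Q^T]} in the orthonormal dialect
#' (\eqn{U G + Q^T Q = I_N}).
#'
#' @param partition an \linkS4class{AreaPartition} (or assignment vector).
#' @param dialect "orthonormal" (default) or "difference".
#' @return a \linkS4class{SlowFastTransform}. Areas of size 1 contribute an
#'   empty Q block; with \eqn{r = 1} the inter-area matrix R has zero rows.
#' @examples
#' tr <- buildTransform(areaPartition(sizes = c(4, 4)))
#' dim(tr@Q)   # 6 x 8
#' @export
buildTransform <- function(partition,
                           dialect = c("orthonormal", "difference")) {
  dialect <- match.arg(dialect)
  if (!is(partition, "AreaPartition"))
    partition <- areaPartition(partition)
  sizes <- areaSizes(partition)
  r <- nAreas(partition)
  N <- sum(sizes)
  U <- .blockDiag(lapply(sizes, function(m) matrix(1, m, 1)))
  Ma <- diag(sizes, nrow = r)
  G <- diag(1 / sizes, nrow = r) %*% t(U)
  qb <- lapply(sizes, function(m) {
    if (m < 2) matrix(0, 0, m)
    else if (dialect == "orthonormal") orthonormalDifferenceMatrix(m)
    else differenceMatrix(m)
  })
  Q <- .blockDiag(qb)
  R <- if (r >= 2) orthonormalDifferenceMatrix(r) else matrix(0, 0, 1)
  C <- R %*% diag(1 / sizes, nrow = r) %*% t(R)
  # slot "C" would partially match new()'s Class argument; name it
  new(Class = "SlowFastTransform", U = U, Ma = Ma, G = G, Q = Q, R = R,
      C = C, dialect = dialect)
}

# right inverse of Q: transpose for orthonormal rows, pseudoinverse else
.qRightInverse <- function(transform) {
  Q <- transform@Q
  if (transform@dialect == "orthonormal") t(Q)
  else t(Q) %*% solve(Q %*% t(Q))
}

#' Build the singularly perturbed two-time-scale system
#'
#' Expresses the linear network dynamics \eqn{\dot x = K x} in slow/fast
#' coordinates. The unscaled blocks are
#' \deqn{\tilde A_{11} = G K^E U, \quad \tilde A_{12} = G K^E Q^T, \quad
#'       \tilde A_{21} = Q K^E U, \quad \tilde A_{22} = Q (K^I + K^E) Q^T,}
#' and the rescaled blocks divide by \eqn{c^I \delta}, \eqn{c^I \delta},
#' \eqn{c^I d} and \eqn{c^I} respectively, placing the slow dynamics in
#' slow time units \eqn{t_s = \delta c^I t}. With the non-orthonormal
#' dialect the pseudoinverse \eqn{Q^+} replaces \eqn{Q^T}.
#'
#' @param network a \linkS4class{ConnectivityNetwork}.
#' @param cI minimum internal link count; computed from the network when
#'   NULL.
#' @param d node parameter; computed (mode "max_ratio") when NULL. Must be
#'   positive (it divides a block).
#' @param delta area parameter; computed when NULL. Must be positive.
#' @param dialect difference-matrix dialect, see
#'   \code{\link{buildTransform}}.
#' @return a \linkS4class{TwoTimeScaleSystem}.
#' @examples
#' sys <- singularPerturbedSystem(example1Network())
#' sys@A11   # [[-1, 1], [1, -1]]
#' @export
singularPerturbedSystem <- function(network, cI = NULL, d = NULL,
                                    delta = NULL,
                                    dialect = c("orthonormal",
                                                "difference")) {
  dialect <- match.arg(dialect)
  sp <- splitConnectionMatrix(network)
  cnt <- .linkCounts(network)
  if (is.null(cI)) cI <- min(cnt$internal)
  if (is.null(d)) d <- nodeParameter(network, "max_ratio")
  if (is.null(delta)) delta <- areaParameter(network)
  if (d <= 0 || delta <= 0)
    stop("d and delta must be positive (they rescale the blocks); ",
         "a network with no external links has no slow/fast separation")
  tr <- buildTransform(partition(network), dialect)
  Qri <- .qRightInverse(tr)
  K <- sp$KI + sp$KE
  A11t <- tr@G %*% sp$KE %*% tr@U
  A12t <- tr@G %*% sp$KE %*% Qri
  A21t <- tr@Q %*% sp$KE %*% tr@U
  A22t <- tr@Q %*% K %*% Qri
  new("TwoTimeScaleSystem",
      A11t = A11t, A12t = A12t, A21t = A21t, A22t = A22t,
      A11 = A11t / (cI * delta), A12 = A12t / (cI * delta),
      A21 = A21t / (cI * d), A22 = A22t / cI,
      cI = cI, d = d, delta = delta, network = network, transform = tr)
}

# eigenvalues sorted by decreasing real part, ties by imaginary part
.sortEigs <- function(values) {
  values <- as.complex(values)
  values[order(-Re(values), Im(values))]
}

#' Reduce to slow and fast subsystems
#'
#' The slow subsystem matrix is
#' \eqn{A_0 = A_{11} - d A_{12} A_{22}^{-1} A_{21}} (slow time units) and
#' the fast subsystem is \eqn{A_{22}} (fast time units). Also fills in the
#' rigid aggregate model \eqn{M_a \dot y_s = K_a y_s} and all three
#' spectra. A numerically singular fast block (condition number above
#' 1e12) makes the reduction uncertifiable.
#'
#' @param system a \linkS4class{TwoTimeScaleSystem}.
#' @return a \linkS4class{ReducedModels}.
#' @examples
#' red <- slowFastSubsystems(singularPerturbedSystem(example1Network()))
#' round(red@A0, 4)    # entries +-0.7634
#' @export
slowFastSubsystems <- function(system) {
  stopifnot(is(system, "TwoTimeScaleSystem"))
  agg <- aggregateSystem(system@network)
  A22 <- system@A22
  r <- nrow(system@A11)
  singular <- nrow(A22) > 0 && kappa(A22, exact = TRUE) > 1e12
  if (singular) {
    A0 <- matrix(NA_real_, r, r)
    slowEigs <- rep(NA_complex_, r)
  } else {
    A0 <- system@A11 -
      system@d * system@A12 %*% solve(A22) %*% system@A21
    slowEigs <- .sortEigs(eigen(A0, only.values = TRUE)$values)
  }
  new("ReducedModels", A0 = A0, A22 = A22, Ka = agg$Ka, Ma = agg$Ma,
      slowEigs = slowEigs,
      fastEigs = .sortEigs(eigen(A22, only.values = TRUE)$values),
      aggregateEigs = agg$aggregateEigs,
      aggregable = !singular,
      reasons = if (singular) "fast subsystem singular" else character())
}

#' Fast-subsystem initial condition correction
#'
#' The fast subsystem evolves from
#' \eqn{z_f(0) = z(0) + d A_{22}^{-1} A_{21} y(0)}, which removes the slow
#' component of the initial fast state.
#'
#' @param system a \linkS4class{TwoTimeScaleSystem}.
#' @param x0 initial node-state vector.
#' @return list with \code{y0}, \code{z0} and corrected \code{zf0}.
#' @export
fastInitialCondition <- function(system, x0) {
  tr <- system@transform
  y0 <- drop(tr@G %*% x0)
  z0 <- drop(tr@Q %*% x0)
  zf0 <- z0 + system@d * drop(solve(system@A22) %*% system@A21 %*% y0)
  list(y0 = y0, z0 = z0, zf0 = zf0)
}

#' Rigid aggregate model
#'
#' The simplified slow model \eqn{M_a \dot y_s = K_a y_s} with
#' \eqn{K_a = U^T K^E U}: each area collapses to one aggregate node whose
#' couplings sum the external links. Reported spectrum is that of
#' \eqn{M_a^{-1} K_a}.
#'
#' @param network a \linkS4class{ConnectivityNetwork}.
#' @return list with \code{Ma}, \code{Ka} and \code{aggregateEigs}.
#' @examples
#' aggregateSystem(example1Network())$Ka   # [[-2, 2], [2, -2]]
#' @export
aggregateSystem <- function(network) {
  sp <- splitConnectionMatrix(network)
  tr <- buildTransform(partition(network))
  Ka <- t(tr@U) %*% sp$KE %*% tr@U
  Ma <- tr@Ma
  eigs <- .sortEigs(eigen(diag(1 / diag(Ma), nrow = nrow(Ma)) %*% Ka,
                          only.values = TRUE)$values)
  list(Ma = Ma, Ka = Ka, aggregateEigs = eigs)
}

#' Check whether a network admits the two-time-scale reduction
#'
#' The separation theorem guarantees the reduction only for sufficiently
#' small \eqn{d} and \eqn{\delta} and a well-posed fast block. The
#' implemented falsifiable check list: the zero-row-sum validation passed;
#' every node has at least one internal link; \eqn{d < 1} and
#' \eqn{\delta < 1}; the fast block \eqn{A_{22}} is nonsingular (condition
#' number at most 1e12) and Hurwitz (all real parts below -1e-9).
#'
#' @param network a \linkS4class{ConnectivityNetwork}.
#' @return list with \code{aggregable} (logical) and \code{reasons}
#'   (character vector of failed checks, empty when aggregable).
#' @examples
#' checkAggregability(example1Network())$aggregable   # TRUE
#' @export
checkAggregability <- function(network) {
  reasons <- character()
  if (!network@conservative)
    reasons <- c(reasons, "connection matrix row sums are not zero")
  cnt <- .linkCounts(network)
  if (any(cnt$internal == 0)) {
    bad <- which(cnt$internal == 0)
    reasons <- c(reasons, paste0(
      "node with zero internal links in area ",
      paste(unique(areaAssignment(network)[bad]), collapse = ", ")))
  } else {
    d <- nodeParameter(network, "max_ratio")
    delta <- areaParameter(network)
    if (d >= 1) reasons <- c(reasons, "node parameter d >= 1")
    if (delta >= 1) reasons <- c(reasons, "area parameter delta >= 1")
    if (d > 0 && delta > 0) {
      sys <- singularPerturbedSystem(network)
      A22 <- sys@A22
      if (nrow(A22) > 0) {
        if (kappa(A22, exact = TRUE) > 1e12)
          reasons <- c(reasons, "fast subsystem singular")
        else {
          ev <- eigen(A22, only.values = TRUE)$values
          if (max(Re(ev)) >= -1e-9)
            reasons <- c(reasons, "fast subsystem not Hurwitz")
        }
      }
    }
  }
  list(aggregable = length(reasons) == 0, reasons = reasons)
}

# complex spectrum -> list of {re, im} pairs for JSON reports
.eigsToJSON <- function(values)
  lapply(as.complex(values),
         function(v) list(re = Re(v), im = Im(v)))

#' Full aggregation report
#'
#' One-stop summary used by the command-line `aggregate` command: sparsity
#' parameters, aggregability verdict, and the slow / fast / rigid
#' aggregate spectra with the reduced matrices.
#'
#' @param network a \linkS4class{ConnectivityNetwork}.
#' @param dialect difference-matrix dialect passed to
#'   \code{\link{singularPerturbedSystem}}.
#' @return named list ready for JSON serialization: d, d_ave, delta, cI,
#'   cE, gammaE, aggregable, reasons, slow_eigs_exact, fast_eigs,
#'   aggregate_eigs, A0, Ka, Ma (matrices as row-major lists with labels).
#' @export
aggregationReport <- function(network,
                              dialect = c("orthonormal", "difference")) {
  dialect <- match.arg(dialect)
  sparsity <- sparsitySummary(network)
  check <- checkAggregability(network)
  agg <- aggregateSystem(network)
  areaLabels <- paste0("area", seq_len(nAreas(network)))
  rep <- list(d = sparsity$d, d_ave = sparsity$d_ave,
              delta = sparsity$delta, cI = sparsity$cI, cE = sparsity$cE,
              gammaE = sparsity$gammaE,
              aggregable = check$aggregable, reasons = check$reasons,
              aggregate_eigs = .eigsToJSON(agg$aggregateEigs),
              Ka = .matrixToJSON(agg$Ka, areaLabels),
              Ma = .matrixToJSON(agg$Ma, areaLabels))
  if (sparsity$d > 0 && sparsity$delta > 0) {
    red <- slowFastSubsystems(singularPerturbedSystem(network,
                                                      dialect = dialect))
    rep$slow_eigs_exact <- .eigsToJSON(red@slowEigs)
    rep$fast_eigs <- .eigsToJSON(red@fastEigs)
    rep$A0 <- .matrixToJSON(red@A0, areaLabels)
  } else {
    rep$slow_eigs_exact <- list()
    rep$fast_eigs <- list()
    rep$A0 <- .matrixToJSON(matrix(0, nAreas(network), nAreas(network)),
                            areaLabels)
  }
  rep
}

.matrixToJSON <- function(M, labels = NULL) {
  list(labels = if (is.null(labels)) paste0("r", seq_len(nrow(M)))
       else labels,
       rows = lapply(seq_len(nrow(M)), function(i) unname(M[i, ])))
}
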