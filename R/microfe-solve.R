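#' @include microfe-model.R
NULL

#' Solve a constrained voxel FE system
#'
#' Low-level entry point shared by [solveFE] and the verification tests.
#' Solves `K u = 0` subject to prescribed values on the given dofs, where
#' `K` is assembled conceptually from one shared element matrix.  Two
#' routes are available: the matrix-free element-by-element
#' Jacobi-preconditioned conjugate-gradient solver (default; scales to
#' millions of dofs), and an assembled-sparse direct factorization through
#' the Matrix package (small meshes, testing).
#'
#' @param connectivity integer 8 x nElements matrix of 1-based node ids.
#' @param Ke 24x24 element stiffness matrix.
#' @param nNodes number of nodes.
#' @param fixedDof 0-based constrained dof indices (node-major x,y,z).
#' @param fixedVal prescribed values (mm), same length.
#' @param tol relative residual tolerance (default 1e-6).
#' @param maxIter iteration cap.
#' @param method `"pcg"` or `"direct"`.
#' @return list with `u` (length 3*nNodes), `iterations`, `relres`,
#'   `converged`.
#' @export
feSolveSystem <- function(connectivity, Ke, nNodes, fixedDof, fixedVal,
                          tol = 1e-6, maxIter = 50000L,
                          method = c("pcg", "direct")) {
  method <- match.arg(method)
  if (method == "pcg") {
    res <- .fePCG(connectivity, Ke, as.integer(nNodes),
                  as.integer(fixedDof), as.numeric(fixedVal),
                  as.numeric(tol), as.integer(maxIter))
    if (!res$converged)
      stop("PCG did not converge within ", maxIter,
           " iterations (relative residual ", format(res$relres), ")")
    return(res)
  }
  K <- .assembleSparse(connectivity, Ke, nNodes)
  ndof <- 3L * nNodes
  fixed <- as.integer(fixedDof) + 1L
  free <- setdiff(seq_len(ndof), fixed)
  u <- numeric(ndof)
  u[fixed] <- fixedVal
  rhs <- -K[free, fixed, drop = FALSE] %*% u[fixed]
  Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
  u[free] <- as.numeric(Matrix::solve(Kff, rhs))
  resid <- K %*% u
  resid[fixed] <- 0
  bnorm <- sqrt(sum(rhs^2))
  list(u = u, iterations = 0L,
       relres = if (bnorm > 0) sqrt(sum(resid^2)) / bnorm else 0,
       converged = TRUE)
}

# Assemble the global sparse stiffness matrix (small meshes / testing).
.assembleSparse <- function(connectivity, Ke, nNodes) {
  nel <- ncol(connectivity)
  dofs <- matrix(0L, 24, nel)
  for (a in 1:8) {
    base <- 3L * (connectivity[a, ] - 1L)
    dofs[3 * a - 2, ] <- base + 1L
    dofs[3 * a - 1, ] <- base + 2L
    dofs[3 * a, ] <- base + 3L
  }
  ii <- dofs[rep(1:24, times = 24), ]
  jj <- dofs[rep(1:24, each = 24), ]
  xx <- rep(as.vector(Ke), nel)
  Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj), x = xx,
                       dims = c(3 * nNodes, 3 * nNodes))
}

#' Solve a micro-FE bending model
#'
#' Runs the constrained linear solve and derives the FE bending stiffness
#' as the summed vertical reaction at the load nodes divided by the
#' prescribed displacement — the same definition as in the physical
#' three-point bending experiment.  The solution is deterministic for a
#' fixed model, and by linearity the stiffness is independent of the
#' magnitude (and sign) of the prescribed displacement and proportional to
#' the tissue modulus.
#'
#' @param model an [FEModel-class].
#' @param tol relative residual tolerance (default 1e-6).
#' @param maxIter iteration cap for the PCG solver.
#' @param method `"pcg"` (matrix-free, default) or `"direct"`
#'   (assembled sparse; small meshes).
#' @return an [FESolution-class].
#' @export
solveFE <- function(model, tol = 1e-6, maxIter = 50000L,
                    method = c("pcg", "direct")) {
  stopifnot(is(model, "FEModel"))
  method <- match.arg(method)
  Ke <- hex8ElementMatrix(model@material, model@elementSizeUm)
  nn <- nrow(model@nodeLattice)
  dir <- .dirichletDofs(model)
  res <- feSolveSystem(model@connectivity, Ke, nn, dir$dof, dir$val,
                       tol = tol, maxIter = maxIter, method = method)
  u <- res$u
  w <- .feMatvec(model@connectivity, Ke, nn, u)
  delta <- model@bc@prescribedDisplacementMm
  zLoad <- 3L * (model@bc@loadNodes - 1L) + 3L  # 1-based z dofs
  reaction <- sum(w[zLoad])
  stiff <- reaction / delta
  if (!is.finite(stiff) || stiff <= 0)
    stop("non-physical FE stiffness (", format(stiff),
         "); check boundary conditions")
  new("FESolution",
      displacements = matrix(u, ncol = 3, byrow = TRUE),
      reactionForceN = reaction, feStiffnessNPerMm = stiff,
      iterations = as.numeric(res$iterations), residual = res$relres,
      converged = res$converged)
}

#' @describeIn solveFE method for the base `solve` generic.
#' @param a an [FEModel-class].
#' @param b unused (the load is part of the model's boundary conditions).
#' @param ... passed on to `solveFE`.
#' @export
setMethod("solve", signature(a = "FEModel", b = "ANY"),
          function(a, b, ...) solveFE(a, ...))

#' Reaction forces of a solved model
#'
#' Vertical reactions recovered as `K u` at the constrained dofs.  Global
#' equilibrium requires the support reactions to balance the load-node
#' reaction.
#'
#' @param model an [FEModel-class].
#' @param solution the matching [FESolution-class].
#' @return list with `loadN`, `supportAN`, `supportBN` (summed vertical
#'   reactions) and `imbalanceN` (their sum).
#' @export
reactionForces <- function(model, solution) {
  Ke <- hex8ElementMatrix(model@material, model@elementSizeUm)
  nn <- nrow(model@nodeLattice)
  u <- as.vector(t(solution@displacements))
  w <- .feMatvec(model@connectivity, Ke, nn, u)
  zs <- function(nodes) sum(w[3L * (nodes - 1L) + 3L])
  load <- zs(model@bc@loadNodes)
  sa <- zs(model@bc@supportNodesA)
  sb <- zs(model@bc@supportNodesB)
  list(loadN = load, supportAN = sa, supportBN = sb,
       imbalanceN = load + sa + sb)
}
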