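# Linear 4-node tetrahedron (constant-strain) elasticity: vectorized sparse
# stiffness assembly, element Cauchy stresses, von Mises equivalent stress.

# per-element shape-function gradients and volumes
element_gradients <- function(nodes, elems) {
  a <- nodes[elems[, 1], , drop = FALSE]
  e1 <- nodes[elems[, 2], , drop = FALSE] - a
  e2 <- nodes[elems[, 3], , drop = FALSE] - a
  e3 <- nodes[elems[, 4], , drop = FALSE] - a
  det <- e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
         e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
         e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])
  if (any(det <= 0)) stop2("inverted element %d", which(det <= 0)[1])
  # rows of inv(J) where J = [e1; e2; e3] columns; grad N_{a+1} = row a of inv(J)^T
  inv <- array(0, c(nrow(elems), 3, 3))
  inv[, 1, 1] <- (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) / det
  inv[, 1, 2] <- (e2[, 3] * e3[, 1] - e2[, 1] * e3[, 3]) / det
  inv[, 1, 3] <- (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1]) / det
  inv[, 2, 1] <- (e1[, 3] * e3[, 2] - e1[, 2] * e3[, 3]) / det
  inv[, 2, 2] <- (e1[, 1] * e3[, 3] - e1[, 3] * e3[, 1]) / det
  inv[, 2, 3] <- (e1[, 2] * e3[, 1] - e1[, 1] * e3[, 2]) / det
  inv[, 3, 1] <- (e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]) / det
  inv[, 3, 2] <- (e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]) / det
  inv[, 3, 3] <- (e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) / det
  # grads G[m, a, i]: gradient of shape function a (1..4), component i
  G <- array(0, c(nrow(elems), 4, 3))
  G[, 2, ] <- inv[, 1, ]
  G[, 3, ] <- inv[, 2, ]
  G[, 4, ] <- inv[, 3, ]
  G[, 1, ] <- -(G[, 2, ] + G[, 3, ] + G[, 4, ])
  list(G = G, V = det / 6)
}

#' Assemble the global sparse stiffness matrix
#'
#' Isotropic linear elasticity on 4-node tetrahedra. The unconstrained matrix
#' is symmetric positive semi-definite with exactly six rigid-body modes per
#' connected body.
#'
#' @param mesh A `sij_mesh`.
#' @param material A `material_model`.
#' @return Sparse symmetric `dgCMatrix` of size 3n x 3n (N/mm).
#' @export
assemble_stiffness <- function(mesh, material) {
  eg <- element_gradients(mesh$nodes, mesh$elems)
  G <- eg$G; V <- eg$V
  E <- material$E; nu <- material$nu
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  m <- nrow(mesh$elems)
  # K_{(a i),(b j)} = V [ lam g_a,i g_b,j + mu g_a,j g_b,i + mu delta_ij (g_a . g_b) ]
  ntrip <- m * 144L
  I <- integer(ntrip); J <- integer(ntrip); X <- numeric(ntrip)
  pos <- 0L
  dof <- function(a, i) 3L * (mesh$elems[, a] - 1L) + i
  for (a in 1:4) for (b in 1:4) {
    gdot <- G[, a, 1] * G[, b, 1] + G[, a, 2] * G[, b, 2] + G[, a, 3] * G[, b, 3]
    for (i in 1:3) for (j in 1:3) {
      val <- V * (lam * G[, a, i] * G[, b, j] + mu * G[, a, j] * G[, b, i] +
                    if (i == j) mu * gdot else 0)
      idx <- pos + seq_len(m)
      I[idx] <- dof(a, i); J[idx] <- dof(b, j); X[idx] <- val
      pos <- pos + m
    }
  }
  ndof <- 3L * nrow(mesh$nodes)
  Matrix::sparseMatrix(i = I, j = J, x = X, dims = c(ndof, ndof))
}

#' Element Cauchy stress tensors from a displacement field
#'
#' Constant-strain evaluation, exact for linear displacement fields.
#'
#' @param mesh A `sij_mesh`.
#' @param material A `material_model`.
#' @param u Nodal displacements, n x 3 (mm).
#' @return m x 6 matrix of stress components
#'   `(s11, s22, s33, s12, s23, s13)` in MPa.
#' @export
element_cauchy_stress <- function(mesh, material, u) {
  eg <- element_gradients(mesh$nodes, mesh$elems)
  G <- eg$G
  m <- nrow(mesh$elems)
  eps <- matrix(0, m, 6)  # e11 e22 e33 g12 g23 g13 (tensor shears, not engineering)
  for (a in 1:4) {
    ua <- u[mesh$elems[, a], , drop = FALSE]
    eps[, 1] <- eps[, 1] + ua[, 1] * G[, a, 1]
    eps[, 2] <- eps[, 2] + ua[, 2] * G[, a, 2]
    eps[, 3] <- eps[, 3] + ua[, 3] * G[, a, 3]
    eps[, 4] <- eps[, 4] + (ua[, 1] * G[, a, 2] + ua[, 2] * G[, a, 1]) / 2
    eps[, 5] <- eps[, 5] + (ua[, 2] * G[, a, 3] + ua[, 3] * G[, a, 2]) / 2
    eps[, 6] <- eps[, 6] + (ua[, 1] * G[, a, 3] + ua[, 3] * G[, a, 1]) / 2
  }
  E <- material$E; nu <- material$nu
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  tr <- eps[, 1] + eps[, 2] + eps[, 3]
  cbind(s11 = lam * tr + 2 * mu * eps[, 1],
        s22 = lam * tr + 2 * mu * eps[, 2],
        s33 = lam * tr + 2 * mu * eps[, 3],
        s12 = 2 * mu * eps[, 4],
        s23 = 2 * mu * eps[, 5],
        s13 = 2 * mu * eps[, 6])
}

#' von Mises equivalent stress
#'
#' @param sigma Either a length-6 vector `(s11, s22, s33, s12, s23, s13)`, a
#'   symmetric 3x3 matrix, or an m x 6 matrix of element stresses.
#' @return Scalar (or vector) von Mises stress, same units as input.
#' @export
von_mises <- function(sigma) {
  if (is.matrix(sigma) && nrow(sigma) == 3 && ncol(sigma) == 3) {
    sigma <- c(sigma[1, 1], sigma[2, 2], sigma[3, 3], sigma[1, 2], sigma[2, 3], sigma[1, 3])
  }
  if (!is.matrix(sigma)) sigma <- matrix(sigma, 1)
  sqrt(0.5 * ((sigma[, 1] - sigma[, 2])^2 + (sigma[, 2] - sigma[, 3])^2 +
                (sigma[, 3] - sigma[, 1])^2) +
         3 * (sigma[, 4]^2 + sigma[, 5]^2 + sigma[, 6]^2))
}
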