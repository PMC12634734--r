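# Shared fixtures, built in code and memoized across test files. Small
# (reduced-resolution) meshes keep module tests quick; the acceptance file
# builds its own configurations.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

small_params <- function(variant = "female_like") {
  morphology_params(variant, resolution = 0.45)
}

small_mesh <- function() memo("small_mesh", build_pelvis_mesh(small_params(), "coarse"))

small_model <- function() memo("small_model", build_sij_model(params = small_params()))

small_state_symxyz <- function() {
  memo("small_state_symxyz",
       solve_quasistatic(small_model(), generic_scenarios()$symmetric_xyz))
}

# single-tetrahedron mesh for element-level checks
one_tet_mesh <- function(nodes = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
  sijfem:::new_sij_mesh(nodes, matrix(1:4, 1), list(), list(), 1L)
}

# independent single-tet stiffness oracle: explicit B-matrix route with
# engineering strains, shape gradients from solving the 4x4 interpolation
# system (distinct code path from the package assembly)
oracle_tet_stiffness <- function(nodes, E, nu) {
  A <- cbind(1, nodes)
  grads <- matrix(0, 4, 3)
  for (a in 1:4) {
    rhs <- numeric(4); rhs[a] <- 1
    coef <- solve(A, rhs)      # N_a = c0 + c1 x + c2 y + c3 z
    grads[a, ] <- coef[2:4]
  }
  V <- abs(det(A)) / 6
  B <- matrix(0, 6, 12)
  for (a in 1:4) {
    c0 <- 3 * (a - 1)
    B[1, c0 + 1] <- grads[a, 1]
    B[2, c0 + 2] <- grads[a, 2]
    B[3, c0 + 3] <- grads[a, 3]
    B[4, c0 + 1] <- grads[a, 2]; B[4, c0 + 2] <- grads[a, 1]
    B[5, c0 + 2] <- grads[a, 3]; B[5, c0 + 3] <- grads[a, 2]
    B[6, c0 + 1] <- grads[a, 3]; B[6, c0 + 3] <- grads[a, 1]
  }
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  V * t(B) %*% D %*% B
}

# minimal spring set between explicit node attachments (for kernel tests)
manual_spring_set <- function(fibers, tension_only = TRUE, linearized = FALSE) {
  structure(list(fibers = fibers, tension_only = tension_only,
                 linearized = linearized), class = "spring_set")
}

fiber_row <- function(node_a, node_b, pa, pb, k, L_ref, group = "test") {
  L <- sqrt(sum((pb - pa)^2))
  data.frame(group = group, side = "right", fiber = 1L,
             node_a = node_a, node_b = node_b,
             ax = pa[1], ay = pa[2], az = pa[3],
             bx = pb[1], by = pb[2], bz = pb[3],
             k = k, L_inst = L, L_ref = L_ref, f_pre = 0,
             stringsAsFactors = FALSE)
}
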