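test_that("default roster matches the literature stiffness table", {
  specs <- default_ligament_specs()
  k <- function(nm) specs[[nm]]$k
  expect_equal(k("ASL_left"), 700)
  expect_equal(k("ISL_right"), 2800)
  expect_equal(k("LPSL_left"), 1000)
  expect_equal(k("PSL_right"), 400)
  expect_equal(k("SS_left"), 1400)
  expect_equal(k("ST_right"), 1500)
  expect_equal(k("gluteus_maximus_left"), 344)
  expect_equal(k("gluteus_medius_right"), 779)
  # pubic symphysis: two fibers of 500 N/mm each
  expect_equal(specs$PS$k, 1000)
  expect_equal(specs$PS$n_fibers, 2L)
  ps <- install_ligament(specs$PS, small_mesh())
  expect_equal(ps$k, c(500, 500))
  # muscles carry no pre-tension by default, ligaments carry 118 N
  expect_equal(specs$gluteus_maximus_left$f_pre, 0)
  expect_equal(specs$ST_right$f_pre, 118)
})

test_that("installed fiber length is the Euclidean landmark distance", {
  mesh <- small_mesh()
  spec <- ligament_spec("ST", "right", 1500,
                        list(c("ST_right_f1_sacrum", "ST_right_f1_ilium")), 0)
  fib <- install_ligament(spec, mesh)
  a <- landmark_coord(mesh, "ST_right_f1_sacrum")
  b <- landmark_coord(mesh, "ST_right_f1_ilium")
  expect_equal(fib$L_inst, sqrt(sum((a - b)^2)))
  expect_equal(fib$L_ref, fib$L_inst)  # no pre-tension requested
  bad <- ligament_spec("XX", "right", 100, list(c("nope_a", "nope_b")), 0)
  expect_error(install_ligament(bad, mesh), "missing landmark 'nope_a'")
})

test_that("pre-tension reference length carries the prescribed force", {
  # sacrotuberous ligament numbers: shortening factor ~99.92%
  L_ref <- pretension_reference_length(1500, 98.33, 118)
  expect_equal(L_ref / 98.33, 0.9992, tolerance = 1e-5)
  expect_equal(spring_axial_force(98.33, L_ref, 1500), 118)
  expect_equal(pretension_reference_length(2800, 50, 118), 49.9578571,
               tolerance = 1e-7)
  expect_equal(pretension_reference_length(1500, 98.33, 0), 98.33)
  expect_error(pretension_reference_length(1, 0.5, 10), "unphysical")
})

test_that("springs are tension-only", {
  expect_equal(spring_axial_force(100, 100, 1500), 0)
  expect_equal(spring_axial_force(99, 100, 1500), 0)   # slack
  expect_equal(spring_axial_force(100 + 0.078667, 100, 1500), 118.0005,
               tolerance = 1e-4)
  # disabling pre-tension gives lambda = 1 on every fiber
  mesh <- small_mesh()
  springs <- build_spring_set(mesh, default_ligament_specs(pretension = FALSE))
  expect_equal(springs$fibers$L_ref, springs$fibers$L_inst)
  springs_pt <- build_spring_set(mesh, default_ligament_specs(pretension = TRUE))
  lig <- !grepl("gluteus", springs_pt$fibers$group)
  expect_true(all(springs_pt$fibers$L_ref[lig] < springs_pt$fibers$L_inst[lig]))
})

test_that("spring residual: slack fibers contribute nothing, taut fibers obey action-reaction", {
  nodes <- rbind(c(0, 0, 0), c(10, 0, 0))
  u0 <- matrix(0, 2, 3)
  slack <- manual_spring_set(fiber_row(1L, 2L, nodes[1, ], nodes[2, ], k = 100,
                                       L_ref = 11))
  rs <- spring_residual_and_tangent(slack, nodes, u0)
  expect_equal(rs$force, matrix(0, 2, 3))
  taut <- manual_spring_set(fiber_row(1L, 2L, nodes[1, ], nodes[2, ], k = 100,
                                      L_ref = 9))
  rt <- spring_residual_and_tangent(taut, nodes, u0)
  expect_equal(rt$fiber$force, 100)               # k (L - L_ref)
  expect_equal(rt$force[1, ], c(100, 0, 0))       # pulled toward the other end
  expect_equal(rt$force[2, ], -rt$force[1, ])     # Newton's third law
})

test_that("spring tangent is the exact derivative (finite-difference check)", {
  set.seed(11)
  nodes <- rbind(c(0, 0, 0), c(10, 5, -3))
  k <- 1500
  ss <- manual_spring_set(fiber_row(1L, 2L, nodes[1, ], nodes[2, ],
                                    k = k, L_ref = 10))
  u <- matrix(rnorm(6, sd = 0.5), 2, 3)
  base <- spring_residual_and_tangent(ss, nodes, u)
  J <- Matrix::sparseMatrix(i = base$tangent$i, j = base$tangent$j,
                            x = base$tangent$x, dims = c(6, 6))
  h <- 1e-6
  for (dof in 1:6) {
    up <- u; up[ceiling(dof / 3), ((dof - 1) %% 3) + 1] <- up[ceiling(dof / 3), ((dof - 1) %% 3) + 1] + h
    um <- u; um[ceiling(dof / 3), ((dof - 1) %% 3) + 1] <- um[ceiling(dof / 3), ((dof - 1) %% 3) + 1] - h
    fd <- (as.vector(t(spring_residual_and_tangent(ss, nodes, up)$force)) -
             as.vector(t(spring_residual_and_tangent(ss, nodes, um)$force))) / (2 * h)
    expect_lt(max(abs(fd + as.numeric(J[, dof]))), 1e-6 * k)
  }
})

test_that("ground-ended fibers balance against the ground reaction", {
  nodes <- rbind(c(0, 0, 0))
  fib <- fiber_row(1L, NA_integer_, nodes[1, ], c(20, 0, 0), k = 50, L_ref = 15)
  ss <- manual_spring_set(fib)
  rs <- spring_residual_and_tangent(ss, nodes, matrix(0, 1, 3))
  expect_equal(rs$force[1, ] + rs$ground_force, c(0, 0, 0))
  expect_equal(rs$fiber$force, 50 * 5)
})

test_that("zero-length fiber in the current configuration errors", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0))
  ss <- manual_spring_set(fiber_row(1L, 2L, nodes[1, ], nodes[2, ], 10, 1))
  u <- rbind(c(0, 0, 0), c(-1, 0, 0))  # endpoints coincide
  expect_error(spring_residual_and_tangent(ss, nodes, u), "zero-length")
})
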