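test_that("surface stress summary statistics", {
  st <- small_state_symxyz()
  # constant synthetic field: all stats collapse to the constant
  st_const <- st
  st_const$vm <- rep(5, length(st$vm))
  s <- surface_stress_summary(st_const, "sij_ilium_left")
  expect_equal(s$mean, 5); expect_equal(s$sd, 0)
  expect_equal(s$median, 5); expect_equal(s$p99, 5)
  expect_error(surface_stress_summary(st, "no_such_surface"), "unknown")
  # p99 by linear interpolation between order statistics
  st_seq <- st
  bf <- sijfem:::boundary_faces(st$mesh$nodes, st$mesh$elems)
  st_seq$vm <- seq_len(nrow(st$mesh$elems))
  # order statistics formula on {1..n}: q99 = 1 + 0.99 (n_el - 1)
  s2 <- surface_stress_summary(st_seq, "sij_ilium_left")
  own <- s2$n_elements
  expect_equal(unname(quantile(seq_len(100), 0.99)), 99.01)
  # real field: median <= p99, sd >= 0
  s3 <- surface_stress_summary(st, "sij_ilium_left")
  expect_lte(s3$median, s3$p99)
  expect_gte(s3$sd, 0)
})

test_that("rigid-fit joint motion recovers imposed transforms exactly", {
  st <- small_state_symxyz()
  mesh <- st$mesh
  zero <- st; zero$u <- matrix(0, nrow(mesh$nodes), 3)
  km0 <- relative_joint_motion(zero, "sij_sacrum_left", "sij_ilium_left")
  expect_equal(km0$translation, 0)
  expect_equal(km0$rotation, 0)
  # both patches under one rigid motion: no relative motion
  th <- 0.05
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  both <- st
  both$u <- mesh$nodes %*% t(R) - mesh$nodes + matrix(c(1, -2, 0.5),
                                                     nrow(mesh$nodes), 3, byrow = TRUE)
  kmb <- relative_joint_motion(both, "sij_sacrum_left", "sij_ilium_left")
  expect_lt(kmb$translation, 1e-8)
  expect_lt(kmb$rotation, 1e-5)  # acos() precision floor near zero angle
  # pure ilium translation of 1 mm in x
  tr <- st
  tr$u <- matrix(0, nrow(mesh$nodes), 3)
  il_nodes <- unique(as.vector(mesh$patches$sij_ilium_left))
  tr$u[il_nodes, 1] <- 1
  kmt <- relative_joint_motion(tr, "sij_sacrum_left", "sij_ilium_left")
  expect_equal(kmt$translation, 1.0, tolerance = 1e-9)
  expect_lt(kmt$rotation, 1e-7)
  # imposed relative rotation comes back at the imposed angle
  rot <- st
  rot$u <- matrix(0, nrow(mesh$nodes), 3)
  cen <- colMeans(mesh$nodes[il_nodes, ])
  rot$u[il_nodes, ] <- sweep(mesh$nodes[il_nodes, ], 2, cen) %*% t(R) -
    sweep(mesh$nodes[il_nodes, ], 2, cen)
  kmr <- relative_joint_motion(rot, "sij_sacrum_left", "sij_ilium_left")
  expect_equal(kmr$rotation, th * 180 / pi, tolerance = 1e-9)
})

test_that("rank-deficient patches are rejected by the rigid fit", {
  st <- small_state_symxyz()
  mesh <- st$mesh
  # collinear fake patch
  st2 <- st
  nds <- order(mesh$nodes[, 1])[1:3]
  st2$mesh$patches$degenerate <- matrix(rep(nds, 2), ncol = 3, byrow = TRUE)
  st2$mesh$nodes[nds, 2:3] <- 0   # force collinearity along x
  expect_error(relative_joint_motion(st2, "degenerate", "sij_ilium_left"),
               "rank-deficient|collinear")
})

test_that("write_report emits deterministic, round-trippable tables", {
  st <- small_state_symxyz()
  sums <- list(sc1 = rbind(surface_stress_summary(st, "sij_ilium_left"),
                           surface_stress_summary(st, "sij_ilium_right")),
               sc2 = rbind(surface_stress_summary(st, "sij_ilium_left"),
                           surface_stress_summary(st, "sij_ilium_right")))
  kins <- list(sc1 = joint_kinematics(st), sc2 = joint_kinematics(st))
  d1 <- file.path(tempfile(), "rep1"); d2 <- file.path(tempfile(), "rep2")
  f1 <- write_report(sums, kins, d1, meta = list(seed = 1))
  f2 <- write_report(sums, kins, d2, meta = list(seed = 1))
  sm <- read.csv(file.path(d1, "stress_mean.csv"))
  expect_equal(dim(sm), c(2L, 3L))   # 2 surfaces x (key + 2 scenarios)
  expect_identical(readLines(file.path(d1, "stress_mean.csv")),
                   readLines(file.path(d2, "stress_mean.csv")))
  js <- jsonlite::read_json(file.path(d1, "report.json"), simplifyVector = TRUE)
  expect_equal(js$meta$seed, 1)
  expect_equal(js$kinematics$sc1$translation, kins$sc1$translation,
               tolerance = 1e-12)
})

test_that("mirror-symmetric model + symmetric load: left/right outputs match", {
  model <- build_sij_model(params = small_params(), noise_sd = 0)
  st <- solve_quasistatic(model, generic_scenarios()$symmetric_z)
  sl <- surface_stress_summary(st, "sij_ilium_left")
  sr <- surface_stress_summary(st, "sij_ilium_right")
  expect_equal(sl$mean, sr$mean, tolerance = 1e-6)
  km <- joint_kinematics(st)
  expect_equal(km$translation[1], km$translation[2], tolerance = 1e-6)
  expect_equal(km$rotation[1], km$rotation[2], tolerance = 1e-6)
})
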