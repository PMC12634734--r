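test_that("the eight generic scenarios carry the printed extreme components", {
  sc <- generic_scenarios()
  expect_length(sc, 8L)
  expect_setequal(names(sc), c("unilateral_x", "unilateral_y", "unilateral_z",
                               "symmetric_x", "symmetric_y", "symmetric_z",
                               "unilateral_xyz", "symmetric_xyz"))
  expect_equal(sc$symmetric_z$force, c(0, 0, 2400))
  expect_equal(sc$symmetric_z$sides, "both")
  expect_equal(sc$unilateral_xyz$force, c(600, 1200, 2400))
  expect_equal(sc$unilateral_xyz$sides, "left_only")
  expect_equal(sc$symmetric_x$force, c(600, 0, 0))
  expect_equal(sc$unilateral_y$force, c(0, 1200, 0))
  expect_error(load_case("bad", c(1, 2, 3), scale = 0), "scale")
})

test_that("synthetic gait curve: exact peaks, five ordered phases, seeded", {
  g <- synth_gait(seed = 0)
  expect_equal(max(abs(g$samples$fx_n)), 600)
  expect_equal(max(abs(g$samples$fy_n)), 1200)
  expect_equal(max(abs(g$samples$fz_n)), 2400)
  expect_length(g$events, 5L)
  expect_identical(names(g$events), c("IHS", "CTO", "swing", "CHS", "ITO"))
  expect_true(all(diff(g$events) > 0))  # ordered within the cycle
  g2 <- synth_gait(seed = 0)
  expect_identical(g$samples, g2$samples)
  g3 <- synth_gait(seed = 42)
  expect_false(identical(g$samples, g3$samples))
  expect_equal(max(abs(g3$samples$fz_n)), 2400)  # peaks hold for any seed
})

test_that("gait CSV round-trips and validates its columns", {
  g <- synth_gait(seed = 1)
  f <- tempfile(fileext = ".csv")
  write_gait_csv(g, f)
  g2 <- load_gait_csv(f)
  expect_equal(g2$samples, g$samples)
  expect_identical(unname(g2$events), unname(g$events))
  # toy 3-row file round-trips sample-for-sample
  toy <- data.frame(time_pct = c(0, 50, 100), fx_n = 1:3, fy_n = 4:6, fz_n = 7:9)
  f2 <- tempfile(fileext = ".csv")
  write.csv(toy, f2, row.names = FALSE)
  g3 <- load_gait_csv(f2)
  expect_equal(nrow(g3$samples), 3L)
  expect_equal(g3$samples$fz_n, c(7, 8, 9))
  # missing column errors by name
  bad <- toy[, c("time_pct", "fx_n", "fy_n")]
  f3 <- tempfile(fileext = ".csv")
  write.csv(bad, f3, row.names = FALSE)
  expect_error(load_gait_csv(f3), "fz_n")
})

test_that("phase loads are curve lookups at the marked events", {
  g <- synth_gait(seed = 0)
  lc <- extract_phase_loads(g)
  expect_length(lc, 5L)
  for (ph in gait_phases()) {
    i <- g$events[[ph]]
    expect_equal(lc[[ph]]$force,
                 as.numeric(g$samples[i, c("fx_n", "fy_n", "fz_n")]))
    expect_equal(lc[[ph]]$sides, "left_only")
    # within the curve envelope
    for (j in 1:3) {
      comp <- g$samples[[j + 1]]
      expect_gte(lc[[ph]]$force[j], min(comp) - 1e-9)
      expect_lte(lc[[ph]]$force[j], max(comp) + 1e-9)
    }
  }
  # constant curve gives five identical loads
  const <- g
  const$samples$fx_n <- 1; const$samples$fy_n <- 2; const$samples$fz_n <- 3
  lcc <- extract_phase_loads(const)
  for (ph in gait_phases()) expect_equal(lcc[[ph]]$force, c(1, 2, 3))
  # unmarked events error
  gbad <- g; gbad$events <- gbad$events[-2]
  expect_error(extract_phase_loads(gbad), "CTO")
})

test_that("boundary conditions fix the lumbosacral surface and remove rigid modes", {
  model <- small_model()
  lumbo <- sort(unique(as.vector(model$mesh$patches$lumbosacral)))
  expect_identical(model$bc$fixed_nodes, lumbo)
  st <- small_state_symxyz()
  expect_lt(max(abs(st$u[lumbo, ])), 1e-14)
  # constrained tangent at the initial state is positive definite
  res <- sijfem:::.residual(model, matrix(0, nrow(model$mesh$nodes), 3),
                            numeric(3 * nrow(model$mesh$nodes)), 0)
  free <- setdiff(seq_len(3 * nrow(model$mesh$nodes)), model$bc$fixed_dofs)
  Js <- as.matrix(Matrix::symmpart(res$J[free, free]))
  ev <- eigen(Js, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  # empty lumbosacral patch is rejected
  broken <- model
  broken$mesh$patches$lumbosacral <- broken$mesh$patches$lumbosacral[0, , drop = FALSE]
  expect_error(apply_boundary_conditions(broken), "lumbosacral")
})

test_that("body-weight scaling scales the nodal load vector exactly", {
  model <- small_model()
  case <- generic_scenarios()$symmetric_xyz
  f1 <- build_load_vector(model, case)
  case$scale <- 1.4
  f2 <- build_load_vector(model, case)
  expect_equal(f2, 1.4 * f1)
  # per-side totals: left x mirrored
  n <- nrow(model$mesh$nodes)
  fm <- matrix(f1, n, 3, byrow = TRUE)
  expect_equal(colSums(fm), c(0, 2400, 4800))
  expect_equal(sum(fm[model$bc$coupling$right, 1]), 600)
  expect_equal(sum(fm[model$bc$coupling$left, 1]), -600)
})
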