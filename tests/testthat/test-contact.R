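test_that("exponential pressure-overclosure law hits both cartilage anchors", {
  expect_equal(pressure_overclosure_exponential(3, 3, 54), 0)
  expect_equal(pressure_overclosure_exponential(0, 3, 54), 54)
  # half clearance: p0 (sqrt(e)-1)/(e-1)
  expect_equal(pressure_overclosure_exponential(1.5, 3, 54), 20.3874,
               tolerance = 1e-4)
  expect_equal(pressure_overclosure_exponential(1.5, 3, 54) / 54,
               (sqrt(exp(1)) - 1) / (exp(1) - 1))
  # pubic symphysis anchors
  expect_equal(pressure_overclosure_exponential(4, 4, 5), 0)
  expect_equal(pressure_overclosure_exponential(0, 4, 5), 5)
})

test_that("linear law shares the anchors; exponential lies below it inside", {
  expect_equal(pressure_overclosure_linear(3, 3, 54), 0)
  expect_equal(pressure_overclosure_linear(0, 3, 54), 54)
  expect_equal(pressure_overclosure_linear(1.5, 3, 54), 27)
  g <- seq(0.05, 2.95, by = 0.05)
  pe <- pressure_overclosure_exponential(g, 3, 54)
  pl <- pressure_overclosure_linear(g, 3, 54)
  expect_true(all(pe < pl))
  # monotone decreasing in clearance, complementarity beyond c0
  expect_true(all(diff(pe) < 0))
  expect_true(all(pressure_overclosure_exponential(seq(3, 10, 0.5), 3, 54) == 0))
})

test_that("gap detection measures signed plane distance with barycentric weights", {
  nodes <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(2, 2, 0))
  tris <- rbind(c(1, 2, 3), c(2, 4, 3))  # z = 0 plane, +z normals
  g <- detect_gaps(rbind(c(0.5, 0.5, 1)), nodes, tris)
  expect_equal(g$gap, 1.0)
  expect_equal(g$tri, 1L)
  g2 <- detect_gaps(rbind(c(0.5, 0.5, -0.25)), nodes, tris)
  expect_equal(g2$gap, -0.25)  # penetration is negative
  # out of search radius -> inactive
  g3 <- detect_gaps(rbind(c(0.5, 0.5, 50)), nodes, tris, search_radius = 10)
  expect_true(is.na(g3$gap))
})

test_that("shared-edge projections use the lowest triangle index, same gap either way", {
  nodes <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(2, 2, 0))
  tris <- rbind(c(1, 2, 3), c(2, 4, 3))
  p <- rbind(c(1, 1, 0.5))  # directly over the shared diagonal edge
  g <- detect_gaps(p, nodes, tris)
  expect_equal(g$tri, 1L)
  # brute force: distance to each triangle individually is identical
  d1 <- sqrt(sum((p - sijfem:::closest_point_tri1(p[1, ], nodes[1, ], nodes[2, ], nodes[3, ])$p)^2))
  d2 <- sqrt(sum((p - sijfem:::closest_point_tri1(p[1, ], nodes[2, ], nodes[4, ], nodes[3, ])$p)^2))
  expect_equal(d1, d2)
  expect_equal(abs(g$gap), d1)
})

test_that("closest-point projection agrees with brute-force sampling", {
  set.seed(5)
  a <- c(0, 0, 0); b <- c(3, 0.5, 0); c_ <- c(1, 2, 1)
  # dense barycentric sampling as the oracle
  wgrid <- expand.grid(w1 = seq(0, 1, 0.02), w2 = seq(0, 1, 0.02))
  wgrid <- wgrid[wgrid$w1 + wgrid$w2 <= 1, ]
  pts_tri <- as.matrix(wgrid$w1) %*% a + as.matrix(wgrid$w2) %*% b +
    as.matrix(1 - wgrid$w1 - wgrid$w2) %*% c_
  for (i in 1:20) {
    q <- rnorm(3, sd = 2)
    cp <- sijfem:::closest_point_tri1(q, a, b, c_)
    d_cp <- sqrt(sum((q - cp$p)^2))
    d_brute <- min(sqrt(rowSums(sweep(pts_tri, 2, q)^2)))
    expect_lte(d_cp, d_brute + 1e-9)
    expect_equal(d_cp, d_brute, tolerance = 0.05)
  }
})

test_that("friction traction is penalty-regularized Coulomb", {
  expect_equal(friction_traction(c(1, 0, 0), p = 0, mu = 0.4), c(0, 0, 0))
  # large slip saturates at mu p
  t_slide <- friction_traction(c(5, 0, 0), p = 10, mu = 0.4, k_t = 100)
  expect_equal(sqrt(sum(t_slide^2)), 4)
  expect_equal(t_slide, c(-4, 0, 0))  # opposes slip
  # small slip: linear in slip
  t_stick <- friction_traction(c(1e-4, 0, 0), p = 10, mu = 0.4, k_t = 100)
  expect_equal(t_stick, c(-0.01, 0, 0))
  # Coulomb bound holds for arbitrary slip
  set.seed(1)
  for (i in 1:25) {
    s <- rnorm(3); p <- runif(1, 0, 20)
    tt <- friction_traction(s, p, 0.4, 100)
    expect_lte(sqrt(sum(tt^2)), 0.4 * p + 1e-12)
  }
})

test_that("contact law constructor validates its anchors", {
  expect_error(contact_law(c0 = 0, p0 = 54), "c0 and p0")
  expect_error(contact_law(c0 = 3, p0 = -1), "c0 and p0")
  expect_error(contact_law(mu = -0.1), "mu")
  laws <- default_contact_pairs()
  expect_equal(laws$sij_left$law$c0, 3)
  expect_equal(laws$sij_left$law$p0, 54)
  expect_equal(laws$pubic_rl$law$c0, 4)
  expect_equal(laws$pubic_rl$law$p0, 5)
  expect_equal(laws$sij_right$law$mu, 0.4)
})

test_that("local contact kernel: complementarity and energy consistency", {
  law <- contact_law("exponential", c0 = 3, p0 = 54, mu = 0.4)
  Xf <- c(0.5, 0.5, 2); Xt <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0))
  w <- c(0.25, 0.25, 0.5)
  # closing path: pressure grows monotonically with overclosure
  gaps <- seq(2.9, 0.1, by = -0.2)
  ps <- vapply(gaps, function(gz) {
    u <- c(0, 0, gz - 2, rep(0, 9))
    sijfem:::contact_local_force(u, Xf, Xt, w, law, A = 1)$pressure
  }, numeric(1))
  expect_true(all(diff(ps) > 0))
  # normal contact work is non-negative along the monotone closing path
  fz <- vapply(gaps, function(gz) {
    u <- c(0, 0, gz - 2, rep(0, 9))
    sijfem:::contact_local_force(u, Xf, Xt, w, law, A = 1)$f[3]
  }, numeric(1))
  work <- sum(-fz[-1] * diff(gaps))   # force opposing closing motion
  expect_gte(work, 0)
  # open beyond c0
  u_open <- c(0, 0, 2, rep(0, 9))
  lf <- sijfem:::contact_local_force(u_open, Xf, Xt, w, law, A = 1)
  expect_equal(lf$pressure, 0)
  expect_equal(lf$f, numeric(12))
  # action-reaction: the 12-dof force vector sums to zero per component
  u_close <- c(0, 0, -1, rep(0, 9))
  lf2 <- sijfem:::contact_local_force(u_close, Xf, Xt, w, law, A = 1)
  fmat <- matrix(lf2$f, 4, 3, byrow = TRUE)
  expect_lt(max(abs(colSums(fmat))), 1e-12)
})
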