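# Quasi-static equilibrium of the coupled system: linear-elastic bone volumes
# plus geometrically updated tension-only springs and softened contact. The
# solve runs in two phases -- (0) pre-tension equilibration with zero external
# load, then (1) incremental external loading -- with Newton iteration and a
# backtracking line search at each increment.

#' Solver settings
#'
#' @param increments Number of equal external-load increments.
#' @param tol_rel Relative residual tolerance; convergence requires
#'   `||r|| < tol_rel * (||F_ext|| + 1 N)`.
#' @param max_iter Maximum Newton iterations per increment.
#' @param max_backtrack Maximum step halvings in the line search.
#' @return A `solver_settings` list.
#' @export
solver_settings <- function(increments = 5L, tol_rel = 1e-6, max_iter = 60L,
                            max_backtrack = 8L) {
  structure(list(increments = as.integer(increments), tol_rel = tol_rel,
                 max_iter = as.integer(max_iter),
                 max_backtrack = as.integer(max_backtrack)),
            class = "solver_settings")
}

#' Assemble an FE model
#'
#' @param mesh A `sij_mesh`.
#' @param material A `material_model`.
#' @param springs A `spring_set` or `NULL`.
#' @param contacts List of `contact_pair`s or `NULL`.
#' @param settings A [solver_settings()].
#' @return An `sij_model` (stiffness assembled and cached).
#' @export
fe_model <- function(mesh, material, springs = NULL, contacts = NULL,
                     settings = solver_settings()) {
  if (!is.null(contacts)) {
    contacts <- lapply(contacts, prepare_contact_pair, mesh = mesh)
  }
  structure(list(mesh = mesh, material = material, springs = springs,
                 contacts = contacts, settings = settings,
                 K = assemble_stiffness(mesh, material),
                 bc = NULL, ref_scale = 1),
            class = "sij_model")
}

#' @export
print.sij_model <- function(x, ...) {
  cat(sprintf("FE model: %d nodes, %d elements, %d spring fibers, %d contact pairs, %s\n",
              nrow(x$mesh$nodes), nrow(x$mesh$elems),
              if (is.null(x$springs)) 0L else nrow(x$springs$fibers),
              length(x$contacts),
              if (is.null(x$bc)) "unconstrained" else "constrained"))
  invisible(x)
}

#' Apply the standard boundary conditions
#'
#' Fixes every lumbosacral-patch node in all three directions (the sacrum is
#' held at the lumbosacral joint surface; muscle ground points are fixed in
#' space by construction) and installs a hip-center load coupling per side:
#' the hip force is distributed over the ilium nodes within
#' `coupling_radius` of the hip-center landmark.
#'
#' @param model An `sij_model`.
#' @param coupling_radius Radius (mm, pre-scale) of the acetabular coupling
#'   region.
#' @return The constrained model.
#' @export
apply_boundary_conditions <- function(model, coupling_radius = 22) {
  mesh <- model$mesh
  lp <- mesh$patches[["lumbosacral"]]
  if (is.null(lp) || nrow(lp) == 0L) stop2("empty lumbosacral patch")
  fixed_nodes <- sort(unique(as.vector(lp)))
  # node -> body map
  node_body <- integer(nrow(mesh$nodes))
  for (b in unique(mesh$body)) {
    node_body[unique(as.vector(mesh$elems[mesh$body == b, ]))] <- b
  }
  r <- coupling_radius * (mesh$params$scale %||% 1)
  coup <- function(center_name, body_id) {
    hc <- landmark_coord(mesh, center_name)
    idx <- which(node_body == body_id)
    d <- row_norms(sweep(mesh$nodes[idx, , drop = FALSE], 2, hc))
    sel <- idx[d <= r]
    if (!length(sel)) sel <- idx[order(d)[1:4]]
    sel
  }
  model$bc <- list(
    fixed_nodes = fixed_nodes,
    fixed_dofs = as.vector(outer(1:3, 3L * (fixed_nodes - 1L), `+`)),
    coupling = list(right = coup("hip_center_right", 2L),
                    left = coup("hip_center_left", 3L))
  )
  model
}

#' External nodal force vector for a load case
#'
#' Per-side hip forces are given in local hip frames whose axes align with
#' the global axes on the right side and mirror the x (medio-lateral) axis on
#' the left, so that identical per-side components produce a
#' mirror-symmetric load. Each side's force is distributed equally over its
#' acetabular coupling nodes.
#'
#' @param model Constrained `sij_model`.
#' @param case A [load_case()].
#' @return Numeric vector of length 3n (N).
#' @export
build_load_vector <- function(model, case) {
  if (is.null(model$bc)) stop2("model has no boundary conditions")
  n <- nrow(model$mesh$nodes)
  fvec <- numeric(3L * n)
  add_side <- function(fvec, nodes, f_global) {
    per <- f_global / length(nodes)
    for (i in 1:3) fvec[3L * (nodes - 1L) + i] <- fvec[3L * (nodes - 1L) + i] + per[i]
    fvec
  }
  f <- case$force * case$scale
  if (case$sides %in% c("both", "right_only")) {
    fvec <- add_side(fvec, model$bc$coupling$right, f)
  }
  if (case$sides %in% c("both", "left_only")) {
    fvec <- add_side(fvec, model$bc$coupling$left, f * c(-1, 1, 1))
  }
  fvec
}

# residual r = lambda*F_ext + F_springs + F_contact - K u, plus tangent
.residual <- function(model, u, fext, lambda, pre_scale = 1, want_tangent = TRUE) {
  n <- nrow(model$mesh$nodes)
  uvec <- as.vector(t(u))
  r <- lambda * fext - as.numeric(model$K %*% uvec)
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  spr <- NULL; con <- NULL
  if (!is.null(model$springs)) {
    spr <- spring_residual_and_tangent(model$springs, model$mesh$nodes, u,
                                       ref_scale = model$ref_scale,
                                       pre_scale = pre_scale)
    r <- r + as.vector(t(spr$force))
    trip_i <- c(trip_i, spr$tangent$i); trip_j <- c(trip_j, spr$tangent$j)
    trip_x <- c(trip_x, spr$tangent$x)
  }
  if (!is.null(model$contacts)) {
    # contact engagement is ramped together with the pre-tension so that the
    # undeformed state is an exact equilibrium at the start of continuation
    con <- contact_residual_and_tangent(model$contacts, model$mesh, u,
                                        want_tangent = want_tangent,
                                        scale = pre_scale)
    r <- r + as.vector(t(con$force))
    trip_i <- c(trip_i, con$tangent$i); trip_j <- c(trip_j, con$tangent$j)
    trip_x <- c(trip_x, con$tangent$x)
  }
  if (!want_tangent) return(list(r = r, J = NULL, springs = spr, contact = con))
  J <- model$K
  if (length(trip_i)) {
    J <- J + Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                                  dims = c(3L * n, 3L * n))
  }
  list(r = r, J = J, springs = spr, contact = con)
}

#' Solve the quasi-static problem for one load case
#'
#' Continuation in two phases: first the ligament pre-tension is ramped to
#' its full value with zero external load, then the external load is ramped
#' in equal increments; Newton iteration with the exact spring tangent, a
#' finite-difference softened-contact tangent and a backtracking line search
#' solves each continuation step, and a step that fails to converge is
#' automatically halved (down to 1/32 of the base increment). Deterministic.
#'
#' @param model Constrained `sij_model` (see [apply_boundary_conditions()]).
#' @param load A [load_case()], or `NULL` for the pre-tension phase only.
#' @param u0 Optional initial displacement guess (n x 3).
#' @return An `sij_state`: nodal displacements `u` (mm), per-fiber spring
#'   forces, per-node contact table, element stresses `sigma` (MPa) and von
#'   Mises `vm`, support reactions, convergence log.
#' @export
solve_quasistatic <- function(model, load = NULL, u0 = NULL) {
  if (is.null(model$bc)) stop2("model is unconstrained; call apply_boundary_conditions()")
  st <- model$settings
  n <- nrow(model$mesh$nodes)
  fext <- if (is.null(load)) numeric(3L * n) else build_load_vector(model, load)
  free <- setdiff(seq_len(3L * n), model$bc$fixed_dofs)
  tol <- st$tol_rel * (sqrt(sum(fext^2)) + 1)
  u <- if (is.null(u0)) matrix(0, n, 3) else u0
  log <- list()
  nonlinear <- !is.null(model$contacts) ||
    (!is.null(model$springs) &&
       (model$springs$tension_only || !isTRUE(model$springs$linearized)))

  no_convergence <- function(t_fail) {
    cl <- do.call(rbind, log)
    cond <- structure(class = c("sij_no_convergence", "error", "condition"),
                      list(message = sprintf(
                        "no convergence at continuation point %.4g (pre %.3g, load %.3g)",
                        t_fail, min(1, t_fail), max(0, t_fail - 1)),
                        call = NULL, log = cl))
    stop(cond)
  }

  # Newton solve at a fixed continuation point; returns u or NULL
  newton <- function(u, lam, pre, inc_id) {
    for (iter in seq_len(st$max_iter + 1L)) {
      res <- .residual(model, u, fext, lam, pre_scale = pre)
      rn <- sqrt(sum(res$r[free]^2))
      log[[length(log) + 1L]] <<- data.frame(increment = inc_id, lambda = lam,
                                             pre_scale = pre, iter = iter - 1L,
                                             residual = rn)
      if (rn < tol) return(u)
      if (iter > st$max_iter) return(NULL)
      Jff <- res$J[free, free, drop = FALSE]
      try_direction <- function(du) {
        step <- 1
        for (bt in seq_len(st$max_backtrack + 1L)) {
          uv <- as.vector(t(u)); uv[free] <- uv[free] + step * du
          u_try <- matrix(uv, n, 3, byrow = TRUE)
          r_try <- .residual(model, u_try, fext, lam, pre_scale = pre,
                             want_tangent = FALSE)$r
          rn_try <- sqrt(sum(r_try[free]^2))
          if (rn_try < rn) return(list(u = u_try, rn = rn_try))
          step <- step / 2
        }
        NULL
      }
      du <- tryCatch(as.numeric(Matrix::solve(Jff, res$r[free])),
                     error = function(e) stop2(
                       "singular tangent system (unconstrained components?): %s",
                       conditionMessage(e)))
      got <- try_direction(du)
      if (is.null(got)) {
        # Newton direction is not a descent direction (the residual is
        # continuous but only piecewise-smooth, e.g. where a contact
        # projection crosses a facet edge); fall back to Levenberg-style
        # regularized directions
        dscale <- mean(abs(Matrix::diag(Jff)))
        for (alpha in c(0.01, 0.1, 1, 10)) {
          Jreg <- Jff + alpha * dscale * Matrix::Diagonal(length(free))
          du <- as.numeric(Matrix::solve(Jreg, res$r[free]))
          got <- try_direction(du)
          if (!is.null(got)) break
        }
        if (is.null(got)) return(NULL)  # stagnated; caller halves the step
      }
      u <- got$u
    }
    NULL
  }

  # adaptive continuation along t in [0, 2]: t <= 1 ramps the pre-tension,
  # t > 1 ramps the external load; failed steps are halved
  eval_at <- function(u, t, inc_id) {
    newton(u, lam = max(0, t - 1), pre = min(1, t), inc_id = inc_id)
  }
  base_step <- if (nonlinear) 1 / st$increments else 1
  has_pre <- !is.null(model$springs) && any(model$springs$fibers$f_pre > 0)
  t <- if (has_pre && nonlinear) 0 else 1
  inc_id <- 0L
  u_new <- eval_at(u, t, inc_id)
  if (is.null(u_new)) no_convergence(t)
  u <- u_new
  t_stops <- c(1, if (!is.null(load)) 2 else numeric(0))
  for (t_target in t_stops) {
    step <- if (t_target <= 1) 1 else base_step
    min_step <- step / 32
    while (t < t_target - 1e-12) {
      t_try <- min(t + step, t_target)
      inc_id <- inc_id + 1L
      u_new <- eval_at(u, t_try, inc_id)
      if (is.null(u_new)) {
        step <- step / 2
        if (step < min_step) no_convergence(t_try)
      } else {
        u <- u_new
        t <- t_try
      }
    }
  }
  res <- .residual(model, u, fext, lambda = if (is.null(load)) 0 else 1,
                   pre_scale = 1)

  # final state quantities
  lam_final <- if (is.null(load)) 0 else 1
  r_full <- res$r
  reactions <- matrix(0, n, 3)
  reactions[model$bc$fixed_nodes, ] <-
    -matrix(r_full, n, 3, byrow = TRUE)[model$bc$fixed_nodes, ]
  sigma <- element_cauchy_stress(model$mesh, model$material, u)
  structure(list(
    u = u, converged = TRUE, log = do.call(rbind, log),
    springs = if (!is.null(res$springs)) res$springs$fiber else NULL,
    ground_force = if (!is.null(res$springs)) res$springs$ground_force else c(0, 0, 0),
    contact = if (!is.null(res$contact)) res$contact$table else NULL,
    sigma = sigma, vm = von_mises(sigma),
    fext = lam_final * fext, reactions = reactions,
    residual = r_full, free_dofs = free, tol = tol,
    mesh = model$mesh, material = model$material, model = model,
    load = load
  ), class = "sij_state")
}

#' @export
print.sij_state <- function(x, ...) {
  cat(sprintf("Solution state: %s, max |u| = %.4g mm, max von Mises = %.4g MPa\n",
              if (x$converged) "converged" else "NOT converged",
              max(abs(x$u)), max(x$vm)))
  invisible(x)
}

#' Global force balance check
#'
#' Sums external loads, support reactions at the fixed lumbosacral nodes and
#' reactions at the fixed spring ground points; at equilibrium the sum
#' vanishes within the solver tolerance. Also verifies internal
#' action-reaction consistency of the assembled forces.
#'
#' @param state An `sij_state`.
#' @return Max absolute component of the total force imbalance (N).
#' @export
check_force_balance <- function(state) {
  n <- nrow(state$u)
  fext_total <- colSums(matrix(state$fext, n, 3, byrow = TRUE))
  react_total <- colSums(state$reactions)
  balance <- fext_total + react_total - state$ground_force
  # identity: sum of the full residual equals fext_total - ground_force
  rsum <- colSums(matrix(state$residual, n, 3, byrow = TRUE))
  stopifnot(max(abs(rsum - (fext_total - state$ground_force))) < 1e-6 * (max(abs(fext_total)) + 1))
  max(abs(balance))
}

#' Build a ready-to-solve pelvis model
#'
#' Convenience constructor running the full chain: geometry, density field,
#' material mapping, ligament installation, contact pairs and boundary
#' conditions.
#'
#' @param params A [morphology_params()].
#' @param refinement Mesh refinement level.
#' @param seed Seed for the density field.
#' @param pretension Apply the 118 N ligament pre-tension.
#' @param f_pre Group pre-tension (N).
#' @param stiffness_scale Multiplier on every ligament/muscle stiffness.
#' @param contact_type `"exponential"`, `"linear"` or `"none"`.
#' @param mu Friction coefficient.
#' @param c0_scale Multiplier on cartilage thicknesses.
#' @param tension_only Springs go slack under compression.
#' @param linearized Evaluate springs as small-displacement linear trusses.
#' @param attachment_shift_x Shift (mm) applied to the gluteal ground-point
#'   x-coordinates (medial negative, lateral positive; mirrored on the left).
#' @param n_classes,poisson Material mapping controls.
#' @param noise_sd Density-field noise level (g/cm^3); 0 gives the
#'   deterministic, mirror-symmetric two-level field.
#' @param settings A [solver_settings()].
#' @return Constrained `sij_model`.
#' @export
build_sij_model <- function(params = morphology_params(), refinement = "coarse",
                            seed = 1L, pretension = TRUE, f_pre = 118,
                            stiffness_scale = 1, contact_type = "exponential",
                            mu = 0.4, c0_scale = 1, tension_only = TRUE,
                            attachment_shift_x = 0, n_classes = 40L,
                            poisson = 0.3, noise_sd = 0.05, linearized = FALSE,
                            settings = solver_settings()) {
  mesh <- build_pelvis_mesh(params, refinement)
  if (attachment_shift_x != 0) {
    for (nm in grep("^gluteus_.*_ground$", names(mesh$landmarks), value = TRUE)) {
      sgn <- if (grepl("_left_", nm)) -1 else 1
      mesh$landmarks[[nm]]$point[1] <- mesh$landmarks[[nm]]$point[1] +
        sgn * attachment_shift_x
    }
  }
  dens <- generate_density_field(mesh, seed = seed, noise_sd = noise_sd)
  mat <- material_model(mesh, dens, n_classes = n_classes, poisson = poisson)
  specs <- default_ligament_specs(pretension = pretension, f_pre = f_pre)
  specs <- lapply(specs, function(s) { s$k <- s$k * stiffness_scale; s })
  springs <- build_spring_set(mesh, specs, tension_only = tension_only,
                              linearized = linearized)
  contacts <- if (identical(contact_type, "none")) NULL else
    default_contact_pairs(type = contact_type, mu = mu, c0_scale = c0_scale)
  model <- fe_model(mesh, mat, springs, contacts, settings)
  apply_boundary_conditions(model)
}
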