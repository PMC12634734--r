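# Tension-only, pre-loaded spring network: seven ligament groups, the pubic
# symphysis and two passive gluteal muscles. Each group is split into one or
# more fibers between attachment landmarks; pre-tension is imposed by
# shortening each fiber's stress-free reference length below its installed
# length so that, held at the installed configuration, the group carries the
# prescribed pre-load.

#' Default ligament and muscle roster
#'
#' Group stiffnesses follow the standard SIJ literature values: ASL 700,
#' ISL 2800, LPSL 1000, PSL 400, SS 1400, ST 1500, PS 2*500 = 1000 N/mm;
#' gluteus maximus 344, gluteus medius 779 N/mm. ASL/ISL/PSL are modelled
#' with 3 fibers each (stiffness split equally), the others with 1; the pubic
#' symphysis has 2 fibers of 500 N/mm. Ligaments default to a 118 N group
#' pre-tension; passive muscles to none.
#'
#' @param side `"left"`, `"right"` or `"both"`.
#' @param pretension Logical: apply the default 118 N group pre-tension to
#'   ligaments.
#' @param f_pre Group pre-tension in N (applied to ligaments when
#'   `pretension` is `TRUE`).
#' @return List of `ligament_spec` objects.
#' @export
default_ligament_specs <- function(side = "both", pretension = TRUE, f_pre = 118) {
  sides <- if (side == "both") c("left", "right") else side
  groups <- list(
    ASL = list(k = 700, fibers = 3), ISL = list(k = 2800, fibers = 3),
    LPSL = list(k = 1000, fibers = 1), PSL = list(k = 400, fibers = 3),
    SS = list(k = 1400, fibers = 1), ST = list(k = 1500, fibers = 1)
  )
  specs <- list()
  for (s in sides) {
    for (g in names(groups)) {
      fb <- groups[[g]]$fibers
      specs[[paste(g, s, sep = "_")]] <- ligament_spec(
        name = g, side = s, k = groups[[g]]$k,
        landmarks = lapply(seq_len(fb), function(f)
          c(sprintf("%s_%s_f%d_sacrum", g, s, f), sprintf("%s_%s_f%d_ilium", g, s, f))),
        f_pre = if (pretension) f_pre else 0)
    }
    for (m in c("gluteus_maximus", "gluteus_medius")) {
      specs[[paste(m, s, sep = "_")]] <- ligament_spec(
        name = m, side = s, k = if (m == "gluteus_maximus") 344 else 779,
        landmarks = list(c(sprintf("%s_%s_ilium", m, s), sprintf("%s_%s_ground", m, s))),
        f_pre = 0)
    }
  }
  specs$PS <- ligament_spec(
    name = "PS", side = "both", k = 1000,
    landmarks = list(c("PS_f1_left", "PS_f1_right"), c("PS_f2_left", "PS_f2_right")),
    f_pre = if (pretension) f_pre else 0)
  specs
}

#' Ligament/muscle group specification
#'
#' @param name Group name (e.g. `"ST"`).
#' @param side `"left"`, `"right"` or `"both"`.
#' @param k Total group stiffness (N/mm), split equally among fibers.
#' @param landmarks List of length-2 character vectors naming the endpoint
#'   landmarks of each fiber.
#' @param f_pre Group pre-tension (N, >= 0), split equally among fibers.
#' @return A `ligament_spec`.
#' @export
ligament_spec <- function(name, side, k, landmarks, f_pre = 0) {
  if (k <= 0) stop2("ligament %s: stiffness must be > 0", name)
  if (f_pre < 0) stop2("ligament %s: pre-tension must be >= 0", name)
  if (length(landmarks) < 1L) stop2("ligament %s: at least one fiber required", name)
  structure(list(name = name, side = side, k = k, landmarks = landmarks,
                 f_pre = f_pre, n_fibers = length(landmarks)),
            class = "ligament_spec")
}

#' Stress-free reference length that realizes a pre-tension
#'
#' Shortens a spring's reference length so that, held at its installed
#' length, it carries exactly `f_pre`: `L_ref = L_inst - f_pre / k`.
#'
#' @param k Spring stiffness (N/mm).
#' @param L_inst Installed length (mm).
#' @param f_pre Pre-tension (N).
#' @return Reference length (mm).
#' @export
pretension_reference_length <- function(k, L_inst, f_pre) {
  if (any(k <= 0) || any(L_inst <= 0)) stop2("k and L_inst must be > 0")
  if (any(f_pre < 0)) stop2("pre-tension must be >= 0")
  if (any(f_pre / k >= L_inst))
    stop2("unphysical shortening: f_pre/k (%.4g) >= installed length (%.4g)",
          max(f_pre / k), min(L_inst))
  L_inst - f_pre / k
}

#' Tension-only spring axial force
#'
#' `F = k * (L - L_ref)` when taut (`L > L_ref`), zero when slack.
#'
#' @param L Current length (mm).
#' @param L_ref Reference (stress-free) length (mm).
#' @param k Stiffness (N/mm).
#' @return Axial force in N (never negative).
#' @export
spring_axial_force <- function(L, L_ref, k) {
  pmax(0, k * (L - L_ref))
}

#' Install a ligament group on a mesh
#'
#' Resolves fiber endpoint landmarks to node attachments (or fixed spatial
#' ground points), computes installed lengths from landmark coordinates, and
#' sets the pre-tensioned reference lengths. Group stiffness and pre-tension
#' are split equally among fibers.
#'
#' @param spec A [ligament_spec()].
#' @param mesh A `sij_mesh` carrying the referenced landmarks.
#' @return Data frame of fibers (one row per fiber) with endpoint node
#'   indices (`NA` for ground points), ground coordinates, `k`, `L_inst`,
#'   `L_ref`, `f_pre`.
#' @export
install_ligament <- function(spec, mesh) {
  k_i <- spec$k / spec$n_fibers
  f_i <- spec$f_pre / spec$n_fibers
  rows <- lapply(seq_len(spec$n_fibers), function(f) {
    nm <- spec$landmarks[[f]]
    for (lname in nm) {
      if (is.null(mesh$landmarks[[lname]]))
        stop2("ligament %s: missing landmark '%s'", spec$name, lname)
    }
    la <- mesh$landmarks[[nm[1]]]; lb <- mesh$landmarks[[nm[2]]]
    L <- sqrt(sum((la$point - lb$point)^2))
    if (L <= 0) stop2("ligament %s fiber %d: zero installed length", spec$name, f)
    data.frame(group = spec$name, side = spec$side, fiber = f,
               node_a = la$node, node_b = lb$node,
               ax = la$point[1], ay = la$point[2], az = la$point[3],
               bx = lb$point[1], by = lb$point[2], bz = lb$point[3],
               k = k_i, L_inst = L,
               L_ref = if (f_i > 0) pretension_reference_length(k_i, L, f_i) else L,
               f_pre = f_i, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build the full spring element set
#'
#' @param mesh A `sij_mesh`.
#' @param specs List of [ligament_spec()]s (default [default_ligament_specs()]).
#' @param tension_only Logical: springs go slack below the reference length
#'   (set `FALSE` for bilateral linear springs in verification problems).
#' @param linearized Logical: evaluate fibers as small-displacement trusses
#'   (fixed direction, elongation projected on the installed axis), making
#'   the spring network exactly linear. Default `FALSE`
#'   (large-displacement kinematics).
#' @return Object of class `spring_set` (data frame of fibers plus behaviour
#'   flags).
#' @export
build_spring_set <- function(mesh, specs = default_ligament_specs(),
                             tension_only = TRUE, linearized = FALSE) {
  fib <- do.call(rbind, lapply(specs, install_ligament, mesh = mesh))
  rownames(fib) <- NULL
  structure(list(fibers = fib, tension_only = tension_only,
                 linearized = linearized), class = "spring_set")
}

#' @export
print.spring_set <- function(x, ...) {
  cat(sprintf("Spring set: %d fibers in %d groups (%s)\n", nrow(x$fibers),
              length(unique(paste(x$fibers$group, x$fibers$side))),
              if (x$tension_only) "tension-only" else "bilateral"))
  invisible(x)
}

# current endpoint positions of all fibers given nodal displacements u (n x 3)
spring_endpoints <- function(springs, nodes, u) {
  fib <- springs$fibers
  pa <- cbind(fib$ax, fib$ay, fib$az)
  pb <- cbind(fib$bx, fib$by, fib$bz)
  ia <- !is.na(fib$node_a); ib <- !is.na(fib$node_b)
  pa[ia, ] <- nodes[fib$node_a[ia], , drop = FALSE] + u[fib$node_a[ia], , drop = FALSE]
  pb[ib, ] <- nodes[fib$node_b[ib], , drop = FALSE] + u[fib$node_b[ib], , drop = FALSE]
  list(pa = pa, pb = pb)
}

#' Spring nodal forces and consistent tangent
#'
#' Evaluates the tension-only spring network in the current (deformed)
#' configuration: nodal force contributions and the exact tangent stiffness
#' (material + geometric) as sparse triplets. Fiber directions update with
#' deformation.
#'
#' @param springs A `spring_set`.
#' @param nodes Reference node coordinates (n x 3).
#' @param u Nodal displacements (n x 3).
#' @param ref_scale Multiplier applied to every fiber's reference length
#'   (sensitivity input).
#' @param pre_scale Pre-tension ramp factor in [0, 1]: interpolates each
#'   effective reference length between the installed length (0, no
#'   pre-load) and the target reference length (1); used by the solver's
#'   continuation.
#' @return List: `force` (n x 3 nodal forces, N), `tangent` (triplets i, j,
#'   x of -dF/du), `fiber` (per-fiber data frame with current length `L`
#'   and axial force `force`), `ground_force` (3-vector net force on fixed
#'   ground points).
#' @export
spring_residual_and_tangent <- function(springs, nodes, u, ref_scale = 1,
                                        pre_scale = 1) {
  fib <- springs$fibers
  linearized <- isTRUE(springs$linearized)
  ep <- spring_endpoints(springs, nodes, u)
  if (linearized) {
    # small-displacement truss: fixed installed direction, elongation is the
    # relative displacement projected on that axis
    ep0 <- spring_endpoints(springs, nodes, matrix(0, nrow(nodes), 3))
    d0 <- ep0$pb - ep0$pa
    dir <- d0 / row_norms(d0)
    L_ref <- fib$L_inst + pre_scale * (fib$L_ref * ref_scale - fib$L_inst)
    elong <- rowSums((ep$pb - ep0$pb - (ep$pa - ep0$pa)) * dir) +
      (fib$L_inst - L_ref)
    L <- L_ref + elong
  } else {
    d <- ep$pb - ep$pa
    L <- row_norms(d)
    if (any(L < 1e-12))
      stop2("zero-length fiber in current configuration (group %s)",
            fib$group[which(L < 1e-12)[1]])
    dir <- d / L
    L_ref <- fib$L_inst + pre_scale * (fib$L_ref * ref_scale - fib$L_inst)
  }
  taut <- if (springs$tension_only) L >= L_ref else rep(TRUE, length(L))
  Fax <- ifelse(taut, fib$k * (L - L_ref), 0)
  if (springs$tension_only) Fax <- pmax(Fax, 0)

  n <- nrow(nodes)
  force <- matrix(0, n, 3)
  ground <- c(0, 0, 0)
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  for (f in seq_along(L)) {
    if (!taut[f] && Fax[f] == 0 && springs$tension_only) next
    dv <- dir[f, ]
    # force on a pulls toward b and vice versa
    fa <- Fax[f] * dv
    na_ <- fib$node_a[f]; nb_ <- fib$node_b[f]
    if (!is.na(na_)) force[na_, ] <- force[na_, ] + fa else ground <- ground + fa
    if (!is.na(nb_)) force[nb_, ] <- force[nb_, ] - fa else ground <- ground - fa
    # tangent block: exact derivative (material + geometric term; the
    # linearized mode has no geometric term)
    Tm <- fib$k[f] * tcrossprod(dv) +
      if (linearized) 0 else (Fax[f] / L[f]) * (diag(3) - tcrossprod(dv))
    dofs_a <- if (!is.na(na_)) (3 * (na_ - 1L) + 1:3) else NULL
    dofs_b <- if (!is.na(nb_)) (3 * (nb_ - 1L) + 1:3) else NULL
    add_block <- function(di, dj, s) {
      ti <<- c(ti, rep(di, each = 3)); tj <<- c(tj, rep(dj, times = 3))
      tx <<- c(tx, as.vector(s * t(Tm)))
    }
    if (!is.null(dofs_a)) add_block(dofs_a, dofs_a, +1)
    if (!is.null(dofs_b)) add_block(dofs_b, dofs_b, +1)
    if (!is.null(dofs_a) && !is.null(dofs_b)) {
      add_block(dofs_a, dofs_b, -1)
      add_block(dofs_b, dofs_a, -1)
    }
  }
  fiber <- data.frame(group = fib$group, side = fib$side, fiber = fib$fiber,
                      k = fib$k, L_inst = fib$L_inst, L_ref = L_ref,
                      L = L, force = Fax, stringsAsFactors = FALSE)
  list(force = force, tangent = list(i = ti, j = tj, x = tx),
       fiber = fiber, ground_force = ground)
}
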