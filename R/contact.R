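# Softened contact between paired joint surfaces: node-to-surface gap
# detection (closest-point projection), exponential or linear
# pressure-overclosure laws anchored at the cartilage thickness (zero
# pressure) and the cartilage modulus (pressure at zero clearance), and
# penalty-regularized Coulomb friction.

#' Contact law definition
#'
#' @param type `"exponential"` or `"linear"`.
#' @param c0 Clearance at zero pressure, i.e. cartilage thickness (mm, > 0).
#' @param p0 Pressure at zero clearance, i.e. cartilage modulus (MPa, > 0).
#' @param mu Friction coefficient (>= 0).
#' @param k_t Stick regularization (MPa per mm of slip).
#' @return A `contact_law`.
#' @export
contact_law <- function(type = c("exponential", "linear"), c0 = 3, p0 = 54,
                        mu = 0.4, k_t = 100) {
  type <- match.arg(type)
  if (c0 <= 0 || p0 <= 0) stop2("c0 and p0 must be > 0")
  if (mu < 0) stop2("mu must be >= 0")
  structure(list(type = type, c0 = c0, p0 = p0, mu = mu, k_t = k_t),
            class = "contact_law")
}

#' Exponential pressure-overclosure law
#'
#' Zero pressure at clearance `c0` (cartilage thickness), pressure `p0`
#' (cartilage modulus) at zero clearance, smooth exponential growth in
#' between: `p(g) = p0 (e^((c0-g)/c0) - 1) / (e - 1)` for `g < c0`.
#'
#' @param g Clearance (mm; negative = penetration).
#' @param c0 Clearance at zero pressure (mm).
#' @param p0 Pressure at zero clearance (MPa).
#' @return Pressure in MPa (>= 0).
#' @export
pressure_overclosure_exponential <- function(g, c0, p0) {
  ifelse(g >= c0, 0, p0 * (exp((c0 - g) / c0) - 1) / (exp(1) - 1))
}

#' Linear pressure-overclosure law
#'
#' Shares both anchors with the exponential law: `p = p0 max(0, c0 - g)/c0`.
#'
#' @inheritParams pressure_overclosure_exponential
#' @return Pressure in MPa (>= 0).
#' @export
pressure_overclosure_linear <- function(g, c0, p0) {
  p0 * pmax(0, c0 - g) / c0
}

contact_pressure <- function(law, g) {
  if (law$type == "exponential") pressure_overclosure_exponential(g, law$c0, law$p0)
  else pressure_overclosure_linear(g, law$c0, law$p0)
}

# dp/dg (negative where engaged)
contact_pressure_slope <- function(law, g) {
  if (law$type == "exponential") {
    ifelse(g >= law$c0, 0,
           -law$p0 / (law$c0 * (exp(1) - 1)) * exp((law$c0 - g) / law$c0))
  } else {
    ifelse(g >= law$c0, 0, -law$p0 / law$c0)
  }
}

#' Penalty-regularized Coulomb friction traction
#'
#' `traction = -min(k_t |slip|, mu p) * slip_direction`; zero for open
#' contact.
#'
#' @param slip Slip vector (mm; matrix rows or single vector).
#' @param p Contact pressure (MPa, >= 0).
#' @param mu Friction coefficient.
#' @param k_t Stick regularization (MPa/mm).
#' @return Tangential traction (MPa), same shape as `slip`.
#' @export
friction_traction <- function(slip, p, mu, k_t = 100) {
  single <- !is.matrix(slip)
  if (single) slip <- matrix(slip, 1)
  s <- row_norms(slip)
  mag <- pmin(k_t * s, mu * p)
  dirs <- slip / ifelse(s > 0, s, 1)
  out <- -mag * dirs
  out[s == 0 | p <= 0, ] <- 0
  if (single) as.numeric(out) else out
}

#' Node-to-surface gap detection
#'
#' Signed closest-point distance from each follower point to a target
#' triangle patch. The sign follows the target's outward normal (positive =
#' separation); ties between triangles are broken deterministically by the
#' lowest triangle index. Points with no projection within `search_radius`
#' are flagged inactive (`NA` gap).
#'
#' @param points Follower points (q x 3).
#' @param nodes Node coordinates the patch triangles refer to (n x 3).
#' @param tris Target patch triangle list (t x 3, outward oriented).
#' @param search_radius Maximum unsigned distance for an active projection.
#' @return List with per-point `gap` (mm, `NA` if inactive), `tri` (chosen
#'   triangle index), `w` (q x 3 barycentric weights), `normal` (q x 3 unit
#'   normals of the chosen triangles).
#' @export
detect_gaps <- function(points, nodes, tris, search_radius = Inf) {
  if (!is.matrix(points)) points <- matrix(points, ncol = 3)
  nt <- nrow(tris)
  if (nt == 0L) stop2("degenerate target patch (no triangles)")
  a <- nodes[tris[, 1], , drop = FALSE]
  b <- nodes[tris[, 2], , drop = FALSE]
  c_ <- nodes[tris[, 3], , drop = FALSE]
  nrm <- cross3(b - a, c_ - a)
  nlen <- row_norms(nrm)
  if (any(nlen < 1e-12)) stop2("degenerate target triangle %d", which(nlen < 1e-12)[1])
  nrm <- nrm / nlen
  q <- nrow(points)
  best_d2 <- rep(Inf, q); best_tri <- rep(NA_integer_, q)
  best_w <- matrix(NA_real_, q, 3); best_cp <- matrix(NA_real_, q, 3)
  for (t in seq_len(nt)) {
    cp <- closest_point_on_triangle(points, a[t, ], b[t, ], c_[t, ])
    dv <- points - cp$p
    d2 <- rowSums(dv * dv)
    upd <- d2 < best_d2 - 1e-12  # strict improvement; earlier (lower) index wins ties
    if (any(upd)) {
      best_d2[upd] <- d2[upd]; best_tri[upd] <- t
      best_w[upd, ] <- cp$w[upd, , drop = FALSE]
      best_cp[upd, ] <- cp$p[upd, , drop = FALSE]
    }
  }
  dist <- sqrt(best_d2)
  sgn <- sign(rowSums((points - best_cp) * nrm[best_tri, , drop = FALSE]))
  sgn[sgn == 0] <- 1
  gap <- sgn * dist
  inactive <- dist > search_radius
  gap[inactive] <- NA_real_
  list(gap = gap, tri = best_tri, w = best_w,
       normal = nrm[best_tri, , drop = FALSE], point = best_cp)
}

# closest point on one triangle for many query points (Ericson's algorithm,
# vectorized); returns the point and its barycentric weights
closest_point_on_triangle <- function(p, a, b, c_) {
  q <- nrow(p)
  ab <- b - a; ac <- c_ - a
  ap <- sweep(p, 2, a)
  d1 <- ap %*% ab; d2 <- ap %*% ac
  bp <- sweep(p, 2, b)
  d3 <- bp %*% ab; d4 <- bp %*% ac
  cp_ <- sweep(p, 2, c_)
  d5 <- cp_ %*% ab; d6 <- cp_ %*% ac
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2
  w <- matrix(0, q, 3)
  done <- rep(FALSE, q)
  set_w <- function(idx, w1, w2, w3) {
    if (any(idx)) {
      w[idx, 1] <<- w1[idx]; w[idx, 2] <<- w2[idx]; w[idx, 3] <<- w3[idx]
      done[idx] <<- TRUE
    }
  }
  one <- rep(1, q); zero <- rep(0, q)
  # vertex regions
  set_w(!done & d1 <= 0 & d2 <= 0, one, zero, zero)
  set_w(!done & d3 >= 0 & d4 <= d3, zero, one, zero)
  set_w(!done & d6 >= 0 & d5 <= d6, zero, zero, one)
  # edge AB
  v_ab <- d1 / (d1 - d3)
  set_w(!done & vc <= 0 & d1 >= 0 & d3 <= 0, 1 - v_ab, v_ab, zero)
  # edge AC
  v_ac <- d2 / (d2 - d6)
  set_w(!done & vb <= 0 & d2 >= 0 & d6 <= 0, 1 - v_ac, zero, v_ac)
  # edge BC
  v_bc <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  set_w(!done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0, zero, 1 - v_bc, v_bc)
  # interior
  denom <- va + vb + vc
  v_in <- vb / denom; w_in <- vc / denom
  set_w(!done, 1 - v_in - w_in, v_in, w_in)
  pt <- w[, 1] * matrix(a, q, 3, byrow = TRUE) +
    w[, 2] * matrix(b, q, 3, byrow = TRUE) +
    w[, 3] * matrix(c_, q, 3, byrow = TRUE)
  list(p = pt, w = w)
}

#' Define a contact pair between two patches
#'
#' @param follower,target Patch names (follower nodes are projected onto the
#'   target surface).
#' @param law A [contact_law()].
#' @param search_radius Projection search radius (mm).
#' @param enabled Logical switch.
#' @param weight Force weight (a symmetric two-pass pair uses two
#'   half-weight passes with follower and target swapped).
#' @return A `contact_pair`.
#' @export
contact_pair <- function(follower, target, law, search_radius = 20,
                         enabled = TRUE, weight = 1) {
  structure(list(follower = follower, target = target, law = law,
                 search_radius = search_radius, enabled = enabled,
                 weight = weight),
            class = "contact_pair")
}

#' Default contact pairs for the pelvis model
#'
#' Both SIJs (cartilage thickness 3 mm, modulus 54 MPa) and the pubic
#' symphysis (4 mm, 5 MPa), friction 0.4, follower on the ilium side.
#'
#' @param type Pressure-overclosure law type.
#' @param mu Friction coefficient.
#' @param c0_scale Multiplier on both cartilage thicknesses (overclosure
#'   sensitivity input).
#' @param k_t Stick regularization (MPa/mm).
#' @return List of three `contact_pair`s.
#' @export
default_contact_pairs <- function(type = "exponential", mu = 0.4, c0_scale = 1,
                                  k_t = 100) {
  sij <- contact_law(type, c0 = 3 * c0_scale, p0 = 54, mu = mu, k_t = k_t)
  pub <- contact_law(type, c0 = 4 * c0_scale, p0 = 5, mu = mu, k_t = k_t)
  # the pubic pair crosses the mid-sagittal plane: run it as a balanced
  # two-pass pair so a mirror-symmetric state produces mirror-symmetric forces
  list(
    sij_left = contact_pair("sij_ilium_left", "sij_sacrum_left", sij),
    sij_right = contact_pair("sij_ilium_right", "sij_sacrum_right", sij),
    pubic_rl = contact_pair("pubic_right", "pubic_left", pub, weight = 0.5),
    pubic_lr = contact_pair("pubic_left", "pubic_right", pub, weight = 0.5)
  )
}

# scalar closest point on a triangle (fast path for the local force kernel)
closest_point_tri1 <- function(p, a, b, c_) {
  ab <- b - a; ac <- c_ - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(list(p = a, w = c(1, 0, 0)))
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(list(p = b, w = c(0, 1, 0)))
  cp_ <- p - c_
  d5 <- sum(ab * cp_); d6 <- sum(ac * cp_)
  if (d6 >= 0 && d5 <= d6) return(list(p = c_, w = c(0, 0, 1)))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    v <- d1 / (d1 - d3)
    return(list(p = a + v * ab, w = c(1 - v, v, 0)))
  }
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    v <- d2 / (d2 - d6)
    return(list(p = a + v * ac, w = c(1 - v, 0, v)))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    v <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(list(p = b + v * (c_ - b), w = c(0, 1 - v, v)))
  }
  denom <- va + vb + vc
  v <- vb / denom; w <- vc / denom
  list(p = a + v * ab + w * ac, w = c(1 - v - w, v, w))
}

# local contact force of one follower node against its paired target
# triangle (small-sliding: barycentric weights fixed in the reference
# configuration, normal follows the deformed triangle):
# uloc = (u_follower, u_t1, u_t2, u_t3) as a 12-vector; returns the 12-vector
# of nodal forces plus gap/pressure/traction info
contact_local_force <- function(uloc, Xf, Xt, w, law, A) {
  xf <- Xf + uloc[1:3]
  xt1 <- Xt[1, ] + uloc[4:6]
  xt2 <- Xt[2, ] + uloc[7:9]
  xt3 <- Xt[3, ] + uloc[10:12]
  ab <- xt2 - xt1; ac <- xt3 - xt1
  nrm <- c(ab[2] * ac[3] - ab[3] * ac[2],
           ab[3] * ac[1] - ab[1] * ac[3],
           ab[1] * ac[2] - ab[2] * ac[1])
  nrm <- nrm / sqrt(sum(nrm * nrm))
  anchor <- w[1] * xt1 + w[2] * xt2 + w[3] * xt3
  g <- sum(nrm * (xf - anchor))
  p <- if (law$type == "exponential") {
    if (g >= law$c0) 0 else law$p0 * (exp((law$c0 - g) / law$c0) - 1) / (exp(1) - 1)
  } else {
    if (g >= law$c0) 0 else law$p0 * (law$c0 - g) / law$c0
  }
  if (p <= 0) {
    return(list(f = numeric(12), gap = g, pressure = 0, traction = 0))
  }
  urel <- uloc[1:3] - w[1] * uloc[4:6] - w[2] * uloc[7:9] - w[3] * uloc[10:12]
  s <- urel - sum(urel * nrm) * nrm
  smag <- sqrt(sum(s * s))
  # smooth Coulomb saturation: slope k_t at zero slip, asymptotic limit mu*p
  # (C1 counterpart of the sharp min(k_t |s|, mu p) law; keeps Newton stable
  # at slip scales far above the stick regularization length)
  if (law$mu > 0) {
    s0 <- law$mu * p / law$k_t
    tt <- -law$mu * p * s / sqrt(smag^2 + s0^2)
  } else {
    tt <- c(0, 0, 0)
  }
  tmag <- sqrt(sum(tt * tt))
  ff <- (p * nrm + tt) * A
  list(f = c(ff, -w[1] * ff, -w[2] * ff, -w[3] * ff),
       gap = g, pressure = p, traction = tmag)
}

# Establish the small-sliding pairing of a contact pair in the reference
# configuration: each follower-patch node is projected once onto the target
# patch (deterministic closest-point projection); the paired triangle,
# barycentric weights and tributary area stay fixed during the solve.
prepare_contact_pair <- function(pair, mesh) {
  fnodes <- sort(unique(as.vector(mesh$patches[[pair$follower]])))
  ftris <- mesh$patches[[pair$follower]]
  tris <- mesh$patches[[pair$target]]
  areas <- tri_areas(mesh$nodes, ftris)
  A <- numeric(nrow(mesh$nodes))
  for (cor in 1:3) {
    at <- tapply(areas / 3, ftris[, cor], sum)
    A[as.integer(names(at))] <- A[as.integer(names(at))] + at
  }
  g <- detect_gaps(mesh$nodes[fnodes, , drop = FALSE], mesh$nodes, tris,
                   pair$search_radius)
  act <- which(!is.na(g$gap))
  pair$pairing <- list(
    node = fnodes[act],
    tri_nodes = matrix(tris[g$tri[act], ], ncol = 3),
    w = g$w[act, , drop = FALSE],
    A = A[fnodes[act]] * (pair$weight %||% 1)
  )
  pair
}

# Evaluate all contact pairs in the deformed configuration: nodal forces,
# tangent triplets (finite-difference local tangents), and a per-node
# contact table. Pairings must have been prepared (see prepare_contact_pair).
contact_residual_and_tangent <- function(pairs, mesh, u, want_tangent = TRUE,
                                         scale = 1) {
  n <- nrow(mesh$nodes)
  force <- matrix(0, n, 3)
  ti <- list(); tj <- list(); tx <- list()
  recs <- list()
  fd_h <- 1e-6
  for (pn in names(pairs)) {
    pr <- pairs[[pn]]
    if (!isTRUE(pr$enabled)) next
    if (is.null(pr$pairing)) pr <- prepare_contact_pair(pr, mesh)
    pg <- pr$pairing
    law <- pr$law
    for (qi in seq_along(pg$node)) {
      nd <- pg$node[qi]
      tnodes <- pg$tri_nodes[qi, ]
      w <- pg$w[qi, ]
      Xf <- mesh$nodes[nd, ]
      Xt <- mesh$nodes[tnodes, , drop = FALSE]
      dofnodes <- c(nd, tnodes)
      uloc <- as.vector(t(u[dofnodes, , drop = FALSE]))
      Aw <- pg$A[qi] * scale
      lf <- contact_local_force(uloc, Xf, Xt, w, law, Aw)
      recs[[length(recs) + 1L]] <- data.frame(
        pair = pn, node = nd, gap = lf$gap, pressure = lf$pressure,
        traction = lf$traction, stringsAsFactors = FALSE)
      if (lf$pressure <= 0) next
      for (jn in 1:4) {
        force[dofnodes[jn], ] <- force[dofnodes[jn], ] + lf$f[3 * (jn - 1) + 1:3]
      }
      if (want_tangent) {
        # local tangent by forward finite differences of the local force
        Jloc <- matrix(0, 12, 12)
        for (kk in 1:12) {
          up <- uloc; up[kk] <- up[kk] + fd_h
          Jloc[, kk] <- (contact_local_force(up, Xf, Xt, w, law, Aw)$f - lf$f) / fd_h
        }
        dofs <- as.vector(t(outer(3L * (dofnodes - 1L), 1:3, `+`)))
        k <- length(ti) + 1L
        ti[[k]] <- rep(dofs, times = 12)
        tj[[k]] <- rep(dofs, each = 12)
        tx[[k]] <- as.vector(-Jloc)
      }
    }
  }
  tab <- if (length(recs)) do.call(rbind, recs) else
    data.frame(pair = character(0), node = integer(0), gap = numeric(0),
               pressure = numeric(0), traction = numeric(0))
  list(force = force,
       tangent = list(i = unlist(ti), j = unlist(tj), x = unlist(tx)),
       table = tab)
}

#' Define a contact pair between two patches
#'
#' @param follower,target Patch names (follower nodes are projected onto the
#'   target surface).
#' @param law A [contact_law()].
#' @param search_radius Projection search radius (mm).
#' @param enabled Logical switch.
#' @param weight Force weight (a symmetric two-pass pair uses two
#'   half-weight passes with follower and target swapped).
#' @return A `contact_pair`.
#' @export
contact_pair <- function(follower, target, law, search_radius = 20,
                         enabled = TRUE, weight = 1) {
  structure(list(follower = follower, target = target, law = law,
                 search_radius = search_radius, enabled = enabled,
                 weight = weight),
            class = "contact_pair")
}

#' Default contact pairs for the pelvis model
#'
#' Both SIJs (cartilage thickness 3 mm, modulus 54 MPa) and the pubic
#' symphysis (4 mm, 5 MPa), friction 0.4, follower on the ilium side.
#'
#' @param type Pressure-overclosure law type.
#' @param mu Friction coefficient.
#' @param c0_scale Multiplier on both cartilage thicknesses (overclosure
#'   sensitivity input).
#' @param k_t Stick regularization (MPa/mm).
#' @return List of three `contact_pair`s.
#' @export
default_contact_pairs <- function(type = "exponential", mu = 0.4, c0_scale = 1,
                                  k_t = 100) {
  sij <- contact_law(type, c0 = 3 * c0_scale, p0 = 54, mu = mu, k_t = k_t)
  pub <- contact_law(type, c0 = 4 * c0_scale, p0 = 5, mu = mu, k_t = k_t)
  # the pubic pair crosses the mid-sagittal plane: run it as a balanced
  # two-pass pair so a mirror-symmetric state produces mirror-symmetric forces
  list(
    sij_left = contact_pair("sij_ilium_left", "sij_sacrum_left", sij),
    sij_right = contact_pair("sij_ilium_right", "sij_sacrum_right", sij),
    pubic_rl = contact_pair("pubic_right", "pubic_left", pub, weight = 0.5),
    pubic_lr = contact_pair("pubic_left", "pubic_right", pub, weight = 0.5)
  )
}
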