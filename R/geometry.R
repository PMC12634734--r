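# Parametric synthetic pelvis geometry: three block-like bone bodies (sacrum,
# two ilia) built from structured hex grids split into tetrahedra, with
# labelled joint surface patches, ligament/muscle attachment landmarks and a
# cortical-shell/trabecular-core density field. The geometry is an idealized
# surrogate, not an anatomical reconstruction: the auricular surfaces are
# near-vertical plates whose inclination and curvature differ between the
# female-like and male-like variants.

# ---- morphology parameters -------------------------------------------------

#' Morphology parameters for the synthetic pelvis
#'
#' Units are mm throughout (global frame: x medio-lateral, y antero-posterior,
#' z cranial-caudal). The two variants differ only in auricular-surface
#' inclination and curvature.
#'
#' @param variant `"female_like"` or `"male_like"`.
#' @param scale Overall uniform scale factor (> 0).
#' @param curvature Auricular-surface curvature parameter (dimensionless);
#'   default depends on variant.
#' @param inclination_deg Auricular-surface inclination about the y axis in
#'   degrees; default depends on variant.
#' @param joint_gap Initial SIJ gap between paired auricular surfaces (mm).
#' @param pubic_gap Initial pubic symphysis gap (mm).
#' @param resolution Mesh density multiplier (1 = desk-scale default).
#' @param seed Integer seed (reserved for seeded fields; the mesh itself is
#'   fully deterministic in the parameters).
#' @return An object of class `morphology_params`.
#' @export
morphology_params <- function(variant = c("female_like", "male_like"),
                              scale = 1, curvature = NULL,
                              inclination_deg = NULL,
                              joint_gap = 2, pubic_gap = 3,
                              resolution = 1, seed = 1L) {
  variant <- match.arg(variant)
  if (!is.numeric(scale) || scale <= 0) stop2("scale must be > 0 (got %s)", scale)
  if (!is.numeric(joint_gap) || joint_gap <= 0)
    stop2("joint_gap must be > 0 (got %s)", joint_gap)
  if (!is.numeric(pubic_gap) || pubic_gap <= 0)
    stop2("pubic_gap must be > 0 (got %s)", pubic_gap)
  if (resolution <= 0) stop2("resolution must be > 0")
  defaults <- if (variant == "female_like") c(curv = 0.25, incl = 6) else c(curv = 0.6, incl = 12)
  structure(list(
    variant = variant, scale = scale,
    curvature = curvature %||% unname(defaults["curv"]),
    inclination_deg = inclination_deg %||% unname(defaults["incl"]),
    joint_gap = joint_gap, pubic_gap = pubic_gap,
    resolution = resolution, seed = as.integer(seed)
  ), class = "morphology_params")
}

#' @export
print.morphology_params <- function(x, ...) {
  cat(sprintf("Morphology params: %s, scale %.3g, curvature %.3g, inclination %.3g deg,\n",
              x$variant, x$scale, x$curvature, x$inclination_deg))
  cat(sprintf("  joint gap %.3g mm, pubic gap %.3g mm, resolution %.3g, seed %d\n",
              x$joint_gap, x$pubic_gap, x$resolution, x$seed))
  invisible(x)
}

# ---- structured grid primitives --------------------------------------------

# grid lines covering consecutive segments between mandatory breakpoints,
# with spacing at most h inside each segment
seg_lines <- function(breaks, h) {
  out <- breaks[1]
  for (i in seq_len(length(breaks) - 1L)) {
    n <- max(1L, ceiling((breaks[i + 1L] - breaks[i]) / h - 1e-9))
    out <- c(out, seq(breaks[i], breaks[i + 1L], length.out = n + 1L)[-1L])
  }
  out
}

# symmetric grid lines about 0 from the positive-side breakpoints
sym_lines <- function(pos_breaks, h) {
  pos <- seg_lines(c(0, pos_breaks), h)
  c(rev(-pos[-1L]), pos)
}

# corner offsets of a hex cell, v0..v7 ordering
.hex_corners <- rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0),
                      c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1))
# five-tet split, two mirror-image parities so face diagonals conform on a
# checkerboard; orientation fixed after assembly
.split_a <- rbind(c(1,2,4,5), c(2,3,4,7), c(2,5,6,7), c(4,5,7,8), c(2,4,5,7))
.split_b <- rbind(c(2,1,3,6), c(1,4,3,8), c(1,6,5,8), c(3,6,8,7), c(1,3,6,8))

# Build a tet mesh on the structured grid (xs, ys, zs), keeping only cells for
# which keep(cx, cy, cz) is TRUE (cell centroids). Returns nodes and
# positively oriented tets.
hex_grid_tets <- function(xs, ys, zs, keep = NULL) {
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  node_id <- function(i, j, k) i + nx * ((j - 1L) + ny * (k - 1L))
  cells <- expand.grid(i = seq_len(nx - 1L), j = seq_len(ny - 1L), k = seq_len(nz - 1L))
  if (!is.null(keep)) {
    cx <- (xs[cells$i] + xs[cells$i + 1L]) / 2
    cy <- (ys[cells$j] + ys[cells$j + 1L]) / 2
    cz <- (zs[cells$k] + zs[cells$k + 1L]) / 2
    cells <- cells[keep(cx, cy, cz), , drop = FALSE]
  }
  m <- nrow(cells)
  if (m == 0L) stop2("empty cell selection")
  corner_ids <- matrix(0L, m, 8L)
  for (c8 in 1:8) {
    corner_ids[, c8] <- node_id(cells$i + .hex_corners[c8, 1],
                                cells$j + .hex_corners[c8, 2],
                                cells$k + .hex_corners[c8, 3])
  }
  parity <- (cells$i + cells$j + cells$k) %% 2L
  elems <- matrix(0L, 5L * m, 4L)
  for (t in 1:5) {
    rows <- seq.int(t, by = 5L, length.out = m)
    sa <- .split_a[t, ]; sb <- .split_b[t, ]
    for (v in 1:4) {
      elems[rows, v] <- ifelse(parity == 0L, corner_ids[, sa[v]], corner_ids[, sb[v]])
    }
  }
  used <- sort(unique(as.vector(elems)))
  remap <- integer(nx * ny * nz)
  remap[used] <- seq_along(used)
  elems <- matrix(remap[elems], ncol = 4L)
  kk <- (used - 1L) %/% (nx * ny); rem <- (used - 1L) %% (nx * ny)
  jj <- rem %/% nx; ii <- rem %% nx
  nodes <- cbind(x = xs[ii + 1L], y = ys[jj + 1L], z = zs[kk + 1L])
  # enforce positive orientation
  v <- tet_volumes_of(nodes, elems)
  neg <- v < 0
  if (any(neg)) elems[neg, c(3, 4)] <- elems[neg, c(4, 3)]
  list(nodes = nodes, elems = elems)
}

tet_volumes_of <- function(nodes, elems) {
  a <- nodes[elems[, 1], , drop = FALSE]
  b <- nodes[elems[, 2], , drop = FALSE] - a
  c_ <- nodes[elems[, 3], , drop = FALSE] - a
  d <- nodes[elems[, 4], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
   b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
   b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

#' Tetrahedron volumes of a mesh
#' @param mesh A `sij_mesh`.
#' @return Numeric vector of signed volumes (mm^3); positive for a valid mesh.
#' @export
tet_volumes <- function(mesh) tet_volumes_of(mesh$nodes, mesh$elems)

# boundary faces of a tet mesh, outward-oriented, with owner element index
boundary_faces <- function(nodes, elems) {
  m <- nrow(elems)
  # faces opposite each local vertex
  fidx <- rbind(c(2, 3, 4), c(1, 3, 4), c(1, 2, 4), c(1, 2, 3))
  faces <- rbind(elems[, fidx[1, ]], elems[, fidx[2, ]],
                 elems[, fidx[3, ]], elems[, fidx[4, ]])
  opp <- c(elems[, 1], elems[, 2], elems[, 3], elems[, 4])
  owner <- rep.int(seq_len(m), 4L)
  key <- apply(faces, 1L, function(r) paste(sort(r), collapse = "_"))
  tab <- table(key)
  bnd <- key %in% names(tab)[tab == 1L]
  faces <- faces[bnd, , drop = FALSE]
  opp <- opp[bnd]; owner <- owner[bnd]
  # orient outward: normal must point away from the opposite vertex
  p <- nodes[faces[, 1], , drop = FALSE]
  q <- nodes[faces[, 2], , drop = FALSE]
  r <- nodes[faces[, 3], , drop = FALSE]
  n <- cross3(q - p, r - p)
  inward <- rowSums(n * (nodes[opp, , drop = FALSE] - p)) > 0
  faces[inward, c(2, 3)] <- faces[inward, c(3, 2)]
  list(faces = faces, owner = owner)
}

tri_centroids <- function(nodes, tris) {
  (nodes[tris[, 1], , drop = FALSE] + nodes[tris[, 2], , drop = FALSE] +
     nodes[tris[, 3], , drop = FALSE]) / 3
}

tri_areas <- function(nodes, tris) {
  p <- nodes[tris[, 1], , drop = FALSE]
  n <- cross3(nodes[tris[, 2], , drop = FALSE] - p,
              nodes[tris[, 3], , drop = FALSE] - p)
  row_norms(n) / 2
}

#' Total area of a named surface patch
#' @param mesh A `sij_mesh`.
#' @param patch Patch name.
#' @return Area in mm^2.
#' @export
patch_area <- function(mesh, patch) {
  tris <- mesh$patches[[patch]]
  if (is.null(tris)) stop2("unknown patch '%s'", patch)
  sum(tri_areas(mesh$nodes, tris))
}

# canonical deterministic ordering of a patch triangle list (by centroid,
# z then y then x) so mirrored patches list corresponding triangles at the
# same positions
order_patch <- function(nodes, tris) {
  cen <- round(tri_centroids(nodes, tris), 6)
  tris[order(cen[, 3], cen[, 2], abs(cen[, 1])), , drop = FALSE]
}

nearest_node_idx <- function(nodes, p) {
  d2 <- (nodes[, 1] - p[1])^2 + (nodes[, 2] - p[2])^2 + (nodes[, 3] - p[3])^2
  which.min(d2)
}

# ---- bone bodies (lattice coordinates, before the morphology mapping) ------

# lattice extents shared by the builders
.lat <- list(
  sac_x = 25, sac_y = c(-25, 15, 25), sac_z = c(0, 20, 70),
  il_w = 35,                       # ilium body width
  il_y = c(-25, 15, 25, 30, 45), il_z = c(0, 10, 20, 30, 70),
  ram_y = c(30, 45), ram_z = c(10, 30),
  aur_y = c(-25, 15), aur_z = c(20, 70),  # auricular window
  zc = 35                          # mapping pivot height
)

build_sacrum <- function(h) {
  xs <- sym_lines(.lat$sac_x, h)
  ys <- seg_lines(.lat$sac_y, h)
  zs <- seg_lines(.lat$sac_z, h)
  if (length(xs) %% 2L == 0L)  # need an even cell count in x for mirror parity
    xs <- sym_lines(.lat$sac_x, h * 0.9)
  hex_grid_tets(xs, ys, zs)
}

build_ilium_right <- function(h, joint_gap, pubic_gap) {
  x_med <- .lat$sac_x + joint_gap
  xs <- seg_lines(c(pubic_gap / 2, x_med, x_med + .lat$il_w), h)
  ys <- seg_lines(.lat$il_y, h)
  zs <- seg_lines(.lat$il_z, h)
  keep <- function(cx, cy, cz) {
    body <- cx > x_med
    ramus <- cx < x_med & cy > .lat$ram_y[1] & cy < .lat$ram_y[2] &
      cz > .lat$ram_z[1] & cz < .lat$ram_z[2]
    body | ramus
  }
  hex_grid_tets(xs, ys, zs, keep)
}

# ---- morphology mapping ----------------------------------------------------

# odd-in-x blend so the mapping is mirror-symmetric and fully engaged at the
# joint surfaces (|x| >= 20)
.map_weight <- function(x) pmax(-1, pmin(1, x / 20))

apply_morphology <- function(coords, params) {
  incl <- tan(params$inclination_deg * pi / 180)
  dz <- coords[, 3] - .lat$zc
  off <- incl * dz + params$curvature * 6 * (dz / 35)^2
  coords[, 1] <- coords[, 1] + .map_weight(coords[, 1]) * off
  coords * params$scale
}

# ---- landmark roster (right side, lattice coordinates) ---------------------

# Each ligament fiber is a pair of attachment targets snapped to the nearest
# mesh node of the owning bone; gluteal ground points and hip centers are free
# spatial points.
landmark_roster_right <- function(joint_gap, pubic_gap) {
  xs <- .lat$sac_x            # 25
  xi <- xs + joint_gap        # ilium medial face
  xl <- xi + .lat$il_w        # ilium lateral face
  lig <- list(
    ASL = list(fibers = 3, sac = cbind(xs - 1, 20, c(30, 40, 50)),
               il = cbind(xi + 1, 20, c(30, 40, 50))),
    ISL = list(fibers = 3, sac = cbind(xs - 1, -20, c(35, 45, 55)),
               il = cbind(xi + 1, -20, c(35, 45, 55))),
    PSL = list(fibers = 3, sac = cbind(xs - 3, -25, c(25, 35, 45)),
               il = cbind(xi + 3, -25, c(25, 35, 45))),
    LPSL = list(fibers = 1, sac = cbind(20, -25, 15), il = cbind(xi + 8, -25, 45)),
    SS = list(fibers = 1, sac = cbind(12, 0, 1), il = cbind(xl - 17, 0, 8)),
    ST = list(fibers = 1, sac = cbind(15, -15, 1), il = cbind(xl - 7, -10, 5))
  )
  ps <- cbind(pubic_gap / 2, 37, c(15, 25))       # on right ilium medial ramus
  muscles <- list(
    gluteus_maximus = list(il = c(xl, -10, 40), ground = c(xl + 18, -25, 0)),
    gluteus_medius = list(il = c(xl, 5, 50), ground = c(xl + 13, 10, 5))
  )
  hip_center <- c(xl - 17, 10, -5)
  list(lig = lig, ps = ps, muscles = muscles, hip_center = hip_center)
}

# ---- mesh container --------------------------------------------------------

new_sij_mesh <- function(nodes, elems, patches, landmarks, body, params = NULL) {
  structure(list(nodes = nodes, elems = elems, patches = patches,
                 landmarks = landmarks, body = body, params = params),
            class = "sij_mesh")
}

#' @export
print.sij_mesh <- function(x, ...) {
  cat(sprintf("Tetrahedral mesh: %d nodes, %d elements, %d patches, %d landmarks\n",
              nrow(x$nodes), nrow(x$elems), length(x$patches), length(x$landmarks)))
  cat("  patches:", paste(names(x$patches), collapse = ", "), "\n")
  invisible(x)
}

#' Names of the surface patches required of a pelvis mesh
#' @return Character vector of the seven patch names.
#' @export
sij_required_patches <- function() {
  c("sij_sacrum_left", "sij_sacrum_right", "sij_ilium_left", "sij_ilium_right",
    "pubic_left", "pubic_right", "lumbosacral")
}

#' Coordinates of a named landmark
#' @param mesh A `sij_mesh`.
#' @param name Landmark name.
#' @return Numeric length-3 point (mm).
#' @export
landmark_coord <- function(mesh, name) {
  lm <- mesh$landmarks[[name]]
  if (is.null(lm)) stop2("unknown landmark '%s'", name)
  lm$point
}

# ---- the pelvis builder ----------------------------------------------------

#' Build the synthetic pelvis mesh
#'
#' Generates sacrum and both ilia as watertight tetrahedral bodies on
#' structured grids, labels the seven standard surface patches
#' (`sij_sacrum_left/right`, `sij_ilium_left/right`, `pubic_left/right`,
#' `lumbosacral`), and places ligament/muscle attachment landmarks plus hip
#' centers. Deterministic in the parameters; the left half is an exact mirror
#' of the right half about the mid-sagittal plane.
#'
#' @param params A [morphology_params()] object.
#' @param refinement One of `"coarse"`, `"medium"`, `"fine"`; element count
#'   grows strictly with refinement.
#' @return A `sij_mesh` with fields `nodes` (n x 3 mm), `elems` (m x 4,
#'   1-based), `patches` (named triangle lists), `landmarks` (named points
#'   with node attachment where applicable) and `body` (per-element bone id:
#'   1 sacrum, 2 right ilium, 3 left ilium).
#' @export
build_pelvis_mesh <- function(params, refinement = c("coarse", "medium", "fine")) {
  if (!inherits(params, "morphology_params")) stop2("params must be morphology_params")
  refinement <- match.arg(refinement)
  fac <- c(coarse = 1, medium = 1.3, fine = 1.7)[[refinement]]
  h <- 11 / (fac * params$resolution)
  gap <- params$joint_gap; pg <- params$pubic_gap

  sac <- build_sacrum(h)
  ilr <- build_ilium_right(h, gap, pg)
  # left ilium: exact mirror of the right one
  ill <- list(nodes = ilr$nodes %*% diag(c(-1, 1, 1)), elems = ilr$elems)
  v <- tet_volumes_of(ill$nodes, ill$elems)
  ill$elems[v < 0, c(3, 4)] <- ill$elems[v < 0, c(4, 3)]
  colnames(ill$nodes) <- colnames(ilr$nodes)

  n_sac <- nrow(sac$nodes); n_ilr <- nrow(ilr$nodes)
  off_ilr <- n_sac; off_ill <- n_sac + n_ilr
  nodes <- rbind(sac$nodes, ilr$nodes, ill$nodes)
  elems <- rbind(sac$elems, ilr$elems + off_ilr, ill$elems + off_ill)
  body <- rep.int(1:3, c(nrow(sac$elems), nrow(ilr$elems), nrow(ill$elems)))

  tol <- 1e-6
  bf_sac <- boundary_faces(sac$nodes, sac$elems)
  bf_ilr <- boundary_faces(ilr$nodes, ilr$elems)
  sel <- function(bf, nds, pred) {
    cen <- tri_centroids(nds, bf$faces)
    bf$faces[pred(cen[, 1], cen[, 2], cen[, 3]), , drop = FALSE]
  }
  aur <- function(y, z) y > .lat$aur_y[1] - tol & y < .lat$aur_y[2] + tol &
    z > .lat$aur_z[1] - tol & z < .lat$aur_z[2] + tol
  x_med <- .lat$sac_x + gap
  sac_r <- order_patch(sac$nodes, sel(bf_sac, sac$nodes, function(x, y, z)
    abs(x - .lat$sac_x) < tol & aur(y, z)))
  sac_l <- order_patch(sac$nodes, sel(bf_sac, sac$nodes, function(x, y, z)
    abs(x + .lat$sac_x) < tol & aur(y, z)))
  lumbo <- order_patch(sac$nodes, sel(bf_sac, sac$nodes, function(x, y, z)
    abs(z - .lat$sac_z[3]) < tol))
  il_r <- order_patch(ilr$nodes, sel(bf_ilr, ilr$nodes, function(x, y, z)
    abs(x - x_med) < tol & aur(y, z)))
  pub_r <- order_patch(ilr$nodes, sel(bf_ilr, ilr$nodes, function(x, y, z)
    abs(x - pg / 2) < tol))
  # left ilium patches share local indices with the right ones (mirror copy);
  # restore outward orientation by swapping two vertices
  swap23 <- function(tr) tr[, c(1, 3, 2), drop = FALSE]
  patches <- list(
    sij_sacrum_right = sac_r,
    sij_sacrum_left = sac_l,
    lumbosacral = lumbo,
    sij_ilium_right = il_r + off_ilr,
    sij_ilium_left = swap23(il_r) + off_ill,
    pubic_right = pub_r + off_ilr,
    pubic_left = swap23(pub_r) + off_ill
  )

  # landmarks: snap right-side targets, mirror to the left via the mirror-copy
  # ilium (same local index) and the sacrum's mirror node map
  ros <- landmark_roster_right(gap, pg)
  sac_mirror <- mirror_node_map(sac$nodes)
  landmarks <- list()
  add_lm <- function(lms, name, node = NA_integer_, point = NULL) {
    pt <- if (is.na(node)) point else nodes[node, ]
    lms[[name]] <- list(point = as.numeric(pt), node = node)
    lms
  }
  for (lg in names(ros$lig)) {
    sp <- ros$lig[[lg]]
    for (f in seq_len(sp$fibers)) {
      ns <- nearest_node_idx(sac$nodes, sp$sac[f, ])
      ni <- nearest_node_idx(ilr$nodes, sp$il[f, ])
      landmarks <- add_lm(landmarks, sprintf("%s_right_f%d_sacrum", lg, f), ns)
      landmarks <- add_lm(landmarks, sprintf("%s_right_f%d_ilium", lg, f), ni + off_ilr)
      landmarks <- add_lm(landmarks, sprintf("%s_left_f%d_sacrum", lg, f), sac_mirror[ns])
      landmarks <- add_lm(landmarks, sprintf("%s_left_f%d_ilium", lg, f), ni + off_ill)
    }
  }
  for (f in seq_len(nrow(ros$ps))) {
    ni <- nearest_node_idx(ilr$nodes, ros$ps[f, ])
    landmarks <- add_lm(landmarks, sprintf("PS_f%d_right", f), ni + off_ilr)
    landmarks <- add_lm(landmarks, sprintf("PS_f%d_left", f), ni + off_ill)
  }
  for (ms in names(ros$muscles)) {
    sp <- ros$muscles[[ms]]
    ni <- nearest_node_idx(ilr$nodes, sp$il)
    landmarks <- add_lm(landmarks, sprintf("%s_right_ilium", ms), ni + off_ilr)
    landmarks <- add_lm(landmarks, sprintf("%s_left_ilium", ms), ni + off_ill)
    landmarks <- add_lm(landmarks, sprintf("%s_right_ground", ms), point = sp$ground)
    landmarks <- add_lm(landmarks, sprintf("%s_left_ground", ms),
                        point = sp$ground * c(-1, 1, 1))
  }
  landmarks <- add_lm(landmarks, "hip_center_right", point = ros$hip_center)
  landmarks <- add_lm(landmarks, "hip_center_left", point = ros$hip_center * c(-1, 1, 1))

  # morphology mapping + uniform scale, applied to nodes and free landmarks
  nodes <- apply_morphology(nodes, params)
  for (nm in names(landmarks)) {
    lm <- landmarks[[nm]]
    landmarks[[nm]]$point <- if (is.na(lm$node)) {
      as.numeric(apply_morphology(matrix(lm$point, 1), params))
    } else nodes[lm$node, ]
  }
  new_sij_mesh(nodes, elems, patches, landmarks, body, params)
}

# node index map under x -> -x reflection (exact for the symmetric grids)
mirror_node_map <- function(nodes) {
  key <- function(m) paste(round(m[, 1], 6), round(m[, 2], 6), round(m[, 3], 6))
  match(key(nodes %*% diag(c(-1, 1, 1))), key(nodes))
}

# ---- simple box mesh (verification geometry) -------------------------------

#' Structured tetrahedral box mesh
#'
#' Utility geometry for verification problems (patch tests, cantilever
#' benchmarks). Face patches are named `xmin`, `xmax`, `ymin`, `ymax`,
#' `zmin`, `zmax`.
#'
#' @param lengths Numeric length-3 box edge lengths (mm).
#' @param divisions Integer length-3 cell counts per axis.
#' @return A `sij_mesh` (no landmarks).
#' @export
tet_grid_box <- function(lengths, divisions) {
  xs <- seq(0, lengths[1], length.out = divisions[1] + 1L)
  ys <- seq(0, lengths[2], length.out = divisions[2] + 1L)
  zs <- seq(0, lengths[3], length.out = divisions[3] + 1L)
  g <- hex_grid_tets(xs, ys, zs)
  bf <- boundary_faces(g$nodes, g$elems)
  cen <- tri_centroids(g$nodes, bf$faces)
  tol <- 1e-9
  pick <- function(i, v) bf$faces[abs(cen[, i] - v) < tol, , drop = FALSE]
  patches <- list(xmin = pick(1, 0), xmax = pick(1, lengths[1]),
                  ymin = pick(2, 0), ymax = pick(2, lengths[2]),
                  zmin = pick(3, 0), zmax = pick(3, lengths[3]))
  new_sij_mesh(g$nodes, g$elems, patches, list(), rep.int(1L, nrow(g$elems)))
}

# ---- density field ---------------------------------------------------------

#' Generate a synthetic apparent-density field
#'
#' Emulates a CT-derived bone density map: elements adjacent to the exterior
#' surface form a stiff cortical shell, interior elements a softer trabecular
#' core, with seeded Gaussian noise. Densities are clamped so that the
#' power-law modulus mapping stays inside the 4315--22608 MPa band of the
#' reference material model.
#'
#' @param mesh A `sij_mesh`.
#' @param seed Integer seed for the noise.
#' @param noise_sd Noise standard deviation in g/cm^3 (0 = deterministic
#'   two-level field).
#' @param shell_mean,core_mean Mean densities (g/cm^3) of shell and core.
#' @return Object of class `density_field` with `rho` (g/cm^3 per element),
#'   `hu` (synthetic CT intensity) and `shell` (logical per element).
#' @export
generate_density_field <- function(mesh, seed = 1L, noise_sd = 0.05,
                                   shell_mean = 2.0, core_mean = 0.9) {
  bf <- boundary_faces(mesh$nodes, mesh$elems)
  shell <- seq_len(nrow(mesh$elems)) %in% bf$owner
  m <- nrow(mesh$elems)
  rho <- ifelse(shell, shell_mean, core_mean)
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    rho <- rho + rnorm(m, sd = noise_sd)
  }
  rho[shell] <- pmin(pmax(rho[shell], 1.6), 2.2065)
  rho[!shell] <- pmin(pmax(rho[!shell], 0.727), 1.2)
  # synthetic CT intensity via the default two-point calibration
  hu <- (rho - 1.0) * 1600
  structure(list(rho = rho, hu = hu, shell = shell, seed = as.integer(seed)),
            class = "density_field")
}

# ---- validation ------------------------------------------------------------

#' Validate structural invariants of a pelvis mesh
#'
#' Checks positive tet orientation, that every patch triangle is a boundary
#' face, landmark name uniqueness, and that the paired SIJ patches are
#' separated by a positive initial gap.
#'
#' @param mesh A `sij_mesh`.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_mesh <- function(mesh) {
  v <- tet_volumes(mesh)
  if (any(v <= 0)) stop2("non-positive tet volume at element %d", which(v <= 0)[1])
  bf <- boundary_faces(mesh$nodes, mesh$elems)
  bkey <- apply(bf$faces, 1, function(r) paste(sort(r), collapse = "_"))
  for (nm in names(mesh$patches)) {
    pk <- apply(mesh$patches[[nm]], 1, function(r) paste(sort(r), collapse = "_"))
    if (!all(pk %in% bkey)) stop2("patch '%s' has non-boundary triangles", nm)
  }
  if (anyDuplicated(names(mesh$landmarks)))
    stop2("duplicate landmark names")
  invisible(TRUE)
}

#' Minimum initial gap between a follower patch's nodes and a target patch
#' @param mesh A `sij_mesh`.
#' @param follower,target Patch names.
#' @return Minimum gap in mm.
#' @export
min_patch_gap <- function(mesh, follower, target) {
  fnodes <- unique(as.vector(mesh$patches[[follower]]))
  g <- detect_gaps(mesh$nodes[fnodes, , drop = FALSE],
                   mesh$nodes, mesh$patches[[target]])
  min(g$gap, na.rm = TRUE)
}
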