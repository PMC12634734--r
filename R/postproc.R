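# Output quantities: surface von Mises stress summaries (mean, sd, median,
# 99th percentile over the elements owning a surface patch) and relative
# joint kinematics from least-squares rigid fits of the paired SIJ patch
# displacement fields.

#' Von Mises stress summary over a surface patch
#'
#' Statistics are computed over the elements that own the patch triangles
#' (unweighted by default; area weighting uses each element's share of patch
#' area). The 99th percentile uses linear interpolation between order
#' statistics.
#'
#' @param state An `sij_state`.
#' @param surface Patch name.
#' @param area_weighted Logical.
#' @return One-row data frame: `surface, n_elements, mean, sd, median, p99`
#'   (MPa).
#' @export
surface_stress_summary <- function(state, surface, area_weighted = FALSE) {
  mesh <- state$mesh
  tris <- mesh$patches[[surface]]
  if (is.null(tris) || nrow(tris) == 0L) stop2("unknown or empty surface '%s'", surface)
  bf <- boundary_faces(mesh$nodes, mesh$elems)
  bkey <- apply(bf$faces, 1, function(r) paste(sort(r), collapse = "_"))
  pkey <- apply(tris, 1, function(r) paste(sort(r), collapse = "_"))
  owners <- bf$owner[match(pkey, bkey)]
  if (anyNA(owners)) stop2("surface '%s' has triangles that are not boundary faces", surface)
  if (area_weighted) {
    w <- tapply(tri_areas(mesh$nodes, tris), owners, sum)
    el <- as.integer(names(w)); w <- as.numeric(w) / sum(w)
    v <- state$vm[el]
    o <- order(v); v <- v[o]; w <- w[o]
    mu <- sum(w * v)
    sdv <- sqrt(sum(w * (v - mu)^2))
    wq <- function(p) {  # weighted quantile, linear in cumulative weight
      cw <- cumsum(w) - w / 2
      if (p <= cw[1]) return(v[1])
      if (p >= cw[length(cw)]) return(v[length(v)])
      stats::approx(cw, v, xout = p)$y
    }
    data.frame(surface = surface, n_elements = length(el), mean = mu, sd = sdv,
               median = wq(0.5), p99 = wq(0.99), stringsAsFactors = FALSE)
  } else {
    el <- unique(owners)
    v <- state$vm[el]
    data.frame(surface = surface, n_elements = length(el), mean = mean(v),
               sd = if (length(v) > 1) sd(v) else 0, median = median(v),
               p99 = unname(quantile(v, 0.99, type = 7)), stringsAsFactors = FALSE)
  }
}

# least-squares rigid fit (Kabsch): reference points X -> displaced X + U
rigid_fit <- function(X, U) {
  if (nrow(X) < 3L) stop2("rigid fit needs at least 3 points")
  Y <- X + U
  xc <- colMeans(X); yc <- colMeans(Y)
  Xc <- sweep(X, 2, xc); Yc <- sweep(Y, 2, yc)
  H <- crossprod(Xc, Yc)
  s <- svd(H)
  if (s$d[2] < 1e-9 * max(s$d[1], 1))
    stop2("rank-deficient rigid fit (collinear patch nodes)")
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- yc - as.numeric(R %*% xc)
  list(R = R, t = t)
}

#' Relative joint kinematics between paired SIJ patches
#'
#' Fits a least-squares rigid transform to each patch's displacement field;
#' the relative transform is the ilium fit composed with the inverse sacrum
#' fit. Translation is the magnitude of the relative motion evaluated at the
#' joint-gap centroid (making it origin-independent); rotation is the total
#' angle of the relative rotation.
#'
#' @param state An `sij_state`.
#' @param sacrum_patch,ilium_patch Patch names.
#' @return One-row data frame: `translation` (mm), `rotation` (deg).
#' @export
relative_joint_motion <- function(state, sacrum_patch, ilium_patch) {
  mesh <- state$mesh
  pn <- function(p) {
    idx <- sort(unique(as.vector(mesh$patches[[p]] %||%
                                   stop2("unknown patch '%s'", p))))
    list(X = mesh$nodes[idx, , drop = FALSE], U = state$u[idx, , drop = FALSE])
  }
  sa <- pn(sacrum_patch); il <- pn(ilium_patch)
  fs <- rigid_fit(sa$X, sa$U)
  fi <- rigid_fit(il$X, il$U)
  # relative transform: ilium motion expressed in the sacrum-fixed frame
  R <- t(fs$R) %*% fi$R
  tr <- as.numeric(t(fs$R) %*% (fi$t - fs$t))
  centroid <- colMeans(rbind(sa$X, il$X))
  d <- as.numeric(R %*% centroid) + tr - centroid
  ang <- acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
  data.frame(translation = sqrt(sum(d^2)), rotation = ang)
}

#' Joint kinematics for both sides
#' @param state An `sij_state`.
#' @return Data frame with `side`, `translation` (mm), `rotation` (deg).
#' @export
joint_kinematics <- function(state) {
  out <- lapply(c("left", "right"), function(s) {
    km <- relative_joint_motion(state, paste0("sij_sacrum_", s),
                                paste0("sij_ilium_", s))
    cbind(data.frame(side = s, stringsAsFactors = FALSE), km)
  })
  do.call(rbind, out)
}

#' Write result tables and metadata
#'
#' Emits one CSV per result table (rows = surfaces or sides, columns =
#' scenarios) and a JSON blob with provenance metadata. Deterministic:
#' regenerating from the same results yields byte-identical files.
#'
#' @param summaries Named list (per scenario) of stress-summary data frames.
#' @param kinematics Named list (per scenario) of [joint_kinematics()] frames.
#' @param path Output directory (created if needed).
#' @param meta List of metadata (seed, config hash, ...) stored in the JSON.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(summaries, kinematics, path, meta = list()) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop2("cannot create report directory '%s'", path)
  pivot <- function(lst, field) {
    scen <- names(lst)
    keycol <- names(lst[[1]])[1]
    keys <- lst[[1]][[keycol]]
    out <- data.frame(key = keys, stringsAsFactors = FALSE)
    names(out) <- keycol
    for (s in scen) out[[s]] <- lst[[s]][[field]]
    out
  }
  paths <- character(0)
  f1 <- file.path(path, "stress_mean.csv")
  write.csv(pivot(summaries, "mean"), f1, row.names = FALSE, quote = FALSE)
  f1b <- file.path(path, "stress_sd.csv")
  write.csv(pivot(summaries, "sd"), f1b, row.names = FALSE, quote = FALSE)
  f2 <- file.path(path, "translations.csv")
  write.csv(pivot(kinematics, "translation"), f2, row.names = FALSE, quote = FALSE)
  f3 <- file.path(path, "rotations.csv")
  write.csv(pivot(kinematics, "rotation"), f3, row.names = FALSE, quote = FALSE)
  f4 <- file.path(path, "report.json")
  payload <- list(meta = meta,
                  summaries = summaries, kinematics = kinematics)
  jsonlite::write_json(payload, f4, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(f1, f1b, f2, f3, f4))
}

#' Export a solution to an ASCII VTU file
#'
#' Writes the tet mesh with nodal displacements (point data) and element von
#' Mises stress (cell data) for visual inspection.
#'
#' @param state An `sij_state`.
#' @param path Output `.vtu` path.
#' @export
write_solution_vtu <- function(state, path) {
  mesh <- state$mesh
  pd <- list(displacement = state$u)
  cd <- list(von_mises = state$vm, body = state$mesh$body)
  write_vtu_raw(mesh$nodes, mesh$elems, path, point_data = pd, cell_data = cd)
  invisible(path)
}
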