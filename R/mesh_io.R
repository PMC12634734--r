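# Mesh input/output. Two ASCII dialects are supported: Gmsh MSH 4.1 (patches
# as 2D physical surface groups, landmarks as named point entities) and VTK
# XML unstructured grids (VTU; patches as per-patch cell-data flag arrays
# over appended triangle cells, landmarks in the CSV sidecar table written
# alongside). write_mesh() %then% read_mesh() round-trips connectivity,
# patches and landmarks exactly (coordinates are printed at full double
# precision).

fmt_g <- function(x) sprintf("%.17g", x)

#' Write a mesh to disk
#'
#' Format chosen by extension: `.msh` (Gmsh 4.1 ASCII) or `.vtu` (VTK XML
#' ASCII). For VTU, landmarks are written to a `<path>_landmarks.csv`
#' sidecar (columns `name,x,y,z,side`); MSH embeds them as point entities.
#'
#' @param mesh A `sij_mesh`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         msh = write_msh(mesh, path),
         vtu = {
           write_vtu_mesh(mesh, path)
           write_landmarks_csv(mesh, landmark_sidecar(path))
         },
         stop2("unsupported mesh format '.%s' (use .msh or .vtu)", ext))
  invisible(path)
}

#' Read a mesh from disk
#'
#' @param path `.msh` or `.vtu` file written by [write_mesh()].
#' @param required_patches Patch names that must be present;
#'   default the seven standard pelvis patches. `NULL` disables the check.
#' @return A `sij_mesh`.
#' @export
read_mesh <- function(path, required_patches = sij_required_patches()) {
  if (!file.exists(path)) stop2("no such file: %s", path)
  ext <- tolower(tools::file_ext(path))
  mesh <- switch(ext,
                 msh = read_msh(path),
                 vtu = {
                   m <- read_vtu_mesh(path)
                   sc <- landmark_sidecar(path)
                   if (file.exists(sc)) m$landmarks <- read_landmarks_csv(sc, m$nodes)
                   m
                 },
                 stop2("unsupported mesh format '.%s'", ext))
  if (!is.null(required_patches)) {
    missing <- setdiff(required_patches, names(mesh$patches))
    if (length(missing))
      stop2("mesh is missing required patch(es): %s", paste(missing, collapse = ", "))
  }
  mesh
}

landmark_sidecar <- function(path) sub("\\.vtu$", "_landmarks.csv", path,
                                       ignore.case = TRUE)

# ---- landmark CSV ----------------------------------------------------------

#' Write the landmark table as CSV
#' @param mesh A `sij_mesh`.
#' @param path Output CSV (`name,x,y,z,side`).
#' @export
write_landmarks_csv <- function(mesh, path) {
  nm <- names(mesh$landmarks)
  side <- ifelse(grepl("left", nm), "left", ifelse(grepl("right", nm), "right", ""))
  pts <- t(vapply(mesh$landmarks, function(l) l$point, numeric(3)))
  df <- data.frame(name = nm, x = fmt_g(pts[, 1]), y = fmt_g(pts[, 2]),
                   z = fmt_g(pts[, 3]), side = side, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_landmarks_csv <- function(path, nodes) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(x = "numeric", y = "numeric", z = "numeric"))
  lms <- list()
  for (i in seq_len(nrow(df))) {
    p <- c(df$x[i], df$y[i], df$z[i])
    ni <- nearest_node_idx(nodes, p)
    attached <- sqrt(sum((nodes[ni, ] - p)^2)) < 1e-9
    lms[[df$name[i]]] <- list(point = p, node = if (attached) ni else NA_integer_)
  }
  lms
}

# ---- Gmsh MSH 4.1 ----------------------------------------------------------

write_msh <- function(mesh, path) {
  patches <- mesh$patches
  lms <- mesh$landmarks
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w("$MeshFormat", "4.1 0 8", "$EndMeshFormat")
  # physical names: points = landmarks, surfaces = patches, one volume
  np <- length(lms); ns <- length(patches)
  w("$PhysicalNames", as.character(np + ns + 1L))
  for (i in seq_along(lms)) w(sprintf('0 %d "%s"', 200L + i, names(lms)[i]))
  for (i in seq_along(patches)) w(sprintf('2 %d "%s"', 100L + i, names(patches)[i]))
  w('3 1 "bones"', "$EndPhysicalNames")
  # entities: landmark point entities carry their coordinates
  bb <- apply(mesh$nodes, 2, range)
  w("$Entities", sprintf("%d 0 %d 1", np, ns))
  for (i in seq_along(lms)) {
    p <- lms[[i]]$point
    w(paste(200L + i, fmt_g(p[1]), fmt_g(p[2]), fmt_g(p[3]), "1", 200L + i))
  }
  for (i in seq_along(patches)) {
    w(paste(100L + i, fmt_g(bb[1, 1]), fmt_g(bb[1, 2]), fmt_g(bb[1, 3]),
            fmt_g(bb[2, 1]), fmt_g(bb[2, 2]), fmt_g(bb[2, 3]), "1", 100L + i, "0"))
  }
  w(paste("1", fmt_g(bb[1, 1]), fmt_g(bb[1, 2]), fmt_g(bb[1, 3]),
          fmt_g(bb[2, 1]), fmt_g(bb[2, 2]), fmt_g(bb[2, 3]), "1", "1", "0"))
  w("$EndEntities")
  n <- nrow(mesh$nodes)
  w("$Nodes", sprintf("1 %d 1 %d", n, n), sprintf("3 1 0 %d", n))
  w(as.character(seq_len(n)))
  w(paste(fmt_g(mesh$nodes[, 1]), fmt_g(mesh$nodes[, 2]), fmt_g(mesh$nodes[, 3])))
  w("$EndNodes")
  # elements: one block of tets + one block per patch
  m <- nrow(mesh$elems)
  ntri <- sum(vapply(patches, nrow, integer(1)))
  w("$Elements", sprintf("%d %d 1 %d", 1L + ns, m + ntri, m + ntri))
  w(sprintf("3 1 4 %d", m))
  w(paste(seq_len(m), mesh$elems[, 1], mesh$elems[, 2], mesh$elems[, 3], mesh$elems[, 4]))
  eid <- m
  for (i in seq_along(patches)) {
    tr <- patches[[i]]
    w(sprintf("2 %d 2 %d", 100L + i, nrow(tr)))
    w(paste(eid + seq_len(nrow(tr)), tr[, 1], tr[, 2], tr[, 3]))
    eid <- eid + nrow(tr)
  }
  w("$EndElements")
  invisible(path)
}

read_msh <- function(path) {
  lines <- readLines(path)
  sec <- function(name) {
    i0 <- which(lines == paste0("$", name)); i1 <- which(lines == paste0("$End", name))
    if (!length(i0)) stop2("MSH file missing $%s section", name)
    lines[(i0 + 1L):(i1 - 1L)]
  }
  # physical names
  pn <- sec("PhysicalNames")[-1L]
  pm <- regmatches(pn, regexec('^(\\d+) (\\d+) "(.*)"$', pn))
  pdim <- vapply(pm, function(x) as.integer(x[2]), integer(1))
  ptag <- vapply(pm, function(x) as.integer(x[3]), integer(1))
  pname <- vapply(pm, function(x) x[4], character(1))
  # entities: collect landmark point coordinates
  ent <- sec("Entities")
  counts <- as.integer(strsplit(ent[1], " ")[[1]])
  lms <- list()
  if (counts[1] > 0) {
    for (i in seq_len(counts[1])) {
      f <- strsplit(ent[1 + i], " ")[[1]]
      tag <- as.integer(f[1])
      nm <- pname[pdim == 0 & ptag == tag]
      lms[[nm]] <- list(point = as.numeric(f[2:4]), node = NA_integer_)
    }
  }
  # nodes
  nd <- sec("Nodes")
  hdr <- as.integer(strsplit(nd[1], " ")[[1]])
  nnode <- hdr[2]
  coords <- nd[(2L + nnode + 1L):(2L + 2L * nnode)]
  nodes <- do.call(rbind, lapply(strsplit(coords, " "), as.numeric))
  colnames(nodes) <- c("x", "y", "z")
  # elements
  el <- sec("Elements")
  nblocks <- as.integer(strsplit(el[1], " ")[[1]])[1]
  pos <- 2L
  elems <- NULL; patches <- list()
  for (b in seq_len(nblocks)) {
    bh <- as.integer(strsplit(el[pos], " ")[[1]])
    dim <- bh[1]; tag <- bh[2]; nel <- bh[4]
    rows <- do.call(rbind, lapply(strsplit(el[pos + seq_len(nel)], " "), as.integer))
    if (dim == 3L) {
      elems <- rows[, 2:5, drop = FALSE]
    } else if (dim == 2L) {
      nm <- pname[pdim == 2 & ptag == tag]
      patches[[nm]] <- rows[, 2:4, drop = FALSE]
    }
    pos <- pos + 1L + nel
  }
  # re-attach landmarks that coincide with mesh nodes
  for (nm in names(lms)) {
    ni <- nearest_node_idx(nodes, lms[[nm]]$point)
    if (sqrt(sum((nodes[ni, ] - lms[[nm]]$point)^2)) < 1e-9) lms[[nm]]$node <- ni
  }
  body <- rep.int(1L, nrow(elems))
  new_sij_mesh(nodes, elems, patches, lms, body)
}

# ---- VTK XML (VTU) ---------------------------------------------------------

# low-level writer: tets plus optional extra triangle cells and data arrays
write_vtu_raw <- function(nodes, elems, path, tri_cells = list(),
                          point_data = list(), cell_data = list()) {
  n <- nrow(nodes); m <- nrow(elems)
  ntri <- sum(vapply(tri_cells, nrow, integer(1)))
  ncell <- m + ntri
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  da <- function(name, type, values, ncomp = 1L) {
    w(sprintf('        <DataArray type="%s" Name="%s" NumberOfComponents="%d" format="ascii">',
              type, name, ncomp))
    w(paste("         ", paste(values, collapse = " ")))
    w("        </DataArray>")
  }
  w('<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="1.0" byte_order="LittleEndian">',
    "  <UnstructuredGrid>",
    sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', n, ncell))
  w("      <Points>")
  da("Points", "Float64", fmt_g(as.vector(t(nodes))), 3L)
  w("      </Points>")
  w("      <Cells>")
  conn <- c(as.vector(t(elems - 1L)),
            unlist(lapply(tri_cells, function(tr) as.vector(t(tr - 1L)))))
  offs <- cumsum(c(rep.int(4L, m), rep.int(3L, ntri)))
  types <- c(rep.int(10L, m), rep.int(5L, ntri))
  da("connectivity", "Int64", conn)
  da("offsets", "Int64", offs)
  da("types", "UInt8", types)
  w("      </Cells>")
  if (length(point_data)) {
    w("      <PointData>")
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v)) da(nm, "Float64", fmt_g(as.vector(t(v))), ncol(v))
      else da(nm, "Float64", fmt_g(v))
    }
    w("      </PointData>")
  }
  if (length(cell_data)) {
    w("      <CellData>")
    for (nm in names(cell_data)) {
      v <- cell_data[[nm]]
      pad <- ncell - length(v)
      if (is.integer(v) || all(v == round(v))) da(nm, "Int32", c(as.integer(v), rep.int(0L, pad)))
      else da(nm, "Float64", fmt_g(c(v, rep(0, pad))))
    }
    w("      </CellData>")
  }
  w("    </Piece>", "  </UnstructuredGrid>", "</VTKFile>")
  invisible(path)
}

write_vtu_mesh <- function(mesh, path) {
  cd <- list(body = c(mesh$body, rep.int(0L, sum(vapply(mesh$patches, nrow, integer(1))))))
  m <- nrow(mesh$elems)
  off <- m
  for (nm in names(mesh$patches)) {
    flag <- integer(m + sum(vapply(mesh$patches, nrow, integer(1))))
    flag[off + seq_len(nrow(mesh$patches[[nm]]))] <- 1L
    cd[[paste0("patch:", nm)]] <- flag
    off <- off + nrow(mesh$patches[[nm]])
  }
  write_vtu_raw(mesh$nodes, mesh$elems, path, tri_cells = mesh$patches,
                cell_data = cd)
}

read_vtu_mesh <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, "//Piece")
  get_da <- function(xpath) {
    nd <- xml2::xml_find_first(piece, xpath)
    if (inherits(nd, "xml_missing")) return(NULL)
    scan(text = xml2::xml_text(nd), quiet = TRUE)
  }
  pts <- get_da(".//Points/DataArray[@Name='Points']")
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)
  colnames(nodes) <- c("x", "y", "z")
  conn <- as.integer(get_da(".//Cells/DataArray[@Name='connectivity']")) + 1L
  offs <- as.integer(get_da(".//Cells/DataArray[@Name='offsets']"))
  types <- as.integer(get_da(".//Cells/DataArray[@Name='types']"))
  starts <- c(0L, offs[-length(offs)])
  tet_idx <- which(types == 10L)
  elems <- t(vapply(tet_idx, function(i) conn[(starts[i] + 1L):offs[i]], integer(4)))
  patches <- list()
  cd_nodes <- xml2::xml_find_all(piece, ".//CellData/DataArray")
  for (nd in cd_nodes) {
    nm <- xml2::xml_attr(nd, "Name")
    if (!startsWith(nm, "patch:")) next
    flag <- as.integer(scan(text = xml2::xml_text(nd), quiet = TRUE))
    sel <- which(flag == 1L & types == 5L)
    patches[[sub("^patch:", "", nm)]] <-
      t(vapply(sel, function(i) conn[(starts[i] + 1L):offs[i]], integer(3)))
  }
  body_nd <- xml2::xml_find_first(piece, ".//CellData/DataArray[@Name='body']")
  body <- if (!inherits(body_nd, "xml_missing")) {
    as.integer(scan(text = xml2::xml_text(body_nd), quiet = TRUE))[tet_idx]
  } else rep.int(1L, nrow(elems))
  new_sij_mesh(nodes, elems, patches, list(), body)
}
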