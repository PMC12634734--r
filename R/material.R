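# Density-based material mapping: CT intensity -> apparent density (linear
# two-point calibration), density -> Young's modulus (power law
# E = 6.950 * rho^1.49, rho in g/cm^3, E in GPa), and binning of the modulus
# field into discrete material classes.

#' Convert CT intensity to apparent density
#'
#' Exact linear interpolation through two (HU, density) calibration anchors;
#' extrapolation below `rho_min` is clamped so densities stay physical.
#'
#' @param hu Numeric CT intensities (HU).
#' @param calib 2 x 2 matrix: rows are the anchors, columns `(hu, rho)`.
#'   Default: 0 HU -> 1.0 g/cm^3, 1600 HU -> 2.0 g/cm^3.
#' @param rho_min Lower clamp for extrapolated densities (g/cm^3).
#' @return Densities in g/cm^3.
#' @export
hu_to_density <- function(hu, calib = cbind(hu = c(0, 1600), rho = c(1, 2)),
                          rho_min = 0.05) {
  calib <- as.matrix(calib)
  if (nrow(calib) != 2L) stop2("calib must have exactly two anchor rows")
  if (calib[1, 1] == calib[2, 1]) stop2("calibration anchors have identical HU")
  slope <- (calib[2, 2] - calib[1, 2]) / (calib[2, 1] - calib[1, 1])
  rho <- calib[1, 2] + slope * (hu - calib[1, 1])
  unname(pmax(rho, rho_min))
}

#' Density to Young's modulus power law
#'
#' E = 6.950 * rho^1.49 with rho in g/cm^3 and E in GPa; strictly monotone
#' increasing.
#'
#' @param rho Apparent densities (g/cm^3), non-negative.
#' @return Young's moduli in GPa.
#' @export
density_to_modulus <- function(rho) {
  if (any(rho < 0)) stop2("negative density")
  6.950 * rho^1.49
}

#' Bin element moduli into discrete material classes
#'
#' Equal-width bins over the observed modulus range; each element is assigned
#' the midpoint of its bin as representative modulus, so the binning error is
#' at most half a bin width.
#'
#' @param E Numeric element moduli (any consistent unit).
#' @param n_classes Number of classes (>= 1), default 40.
#' @return List with `class` (1-based class index per element), `E_class`
#'   (representative modulus per element), `representatives` (per class),
#'   `breaks` and `bin_width`.
#' @export
bin_material_classes <- function(E, n_classes = 40L) {
  if (length(E) == 0L) stop2("empty modulus array")
  if (n_classes < 1L) stop2("n_classes must be >= 1")
  lo <- min(E); hi <- max(E)
  if (hi == lo) {
    reps <- rep(lo, n_classes)
    return(list(class = rep.int(1L, length(E)), E_class = rep(lo, length(E)),
                representatives = reps, breaks = seq(lo, lo, length.out = n_classes + 1L),
                bin_width = 0))
  }
  bw <- (hi - lo) / n_classes
  cls <- pmin(pmax(floor((E - lo) / bw) + 1L, 1L), n_classes)
  reps <- lo + (seq_len(n_classes) - 0.5) * bw
  list(class = as.integer(cls), E_class = reps[cls], representatives = reps,
       breaks = seq(lo, hi, length.out = n_classes + 1L), bin_width = bw)
}

#' Build the per-element material model
#'
#' Maps a density field through the power law, converts to MPa (mm/N/MPa unit
#' system) and bins into material classes.
#'
#' @param mesh A `sij_mesh`.
#' @param density A `density_field` (or numeric densities in g/cm^3).
#' @param n_classes Number of material classes.
#' @param poisson Poisson ratio (single global value).
#' @return Object of class `material_model` with `E` (binned element moduli,
#'   MPa), `E_raw` (unbinned, MPa), `class`, `nu`.
#' @export
material_model <- function(mesh, density, n_classes = 40L, poisson = 0.3) {
  rho <- if (inherits(density, "density_field")) density$rho else as.numeric(density)
  if (length(rho) != nrow(mesh$elems))
    stop2("density field length %d != element count %d", length(rho), nrow(mesh$elems))
  E_mpa <- density_to_modulus(rho) * 1000
  b <- bin_material_classes(E_mpa, n_classes)
  structure(list(E = b$E_class, E_raw = E_mpa, class = b$class,
                 representatives = b$representatives, nu = poisson,
                 n_classes = as.integer(n_classes)),
            class = "material_model")
}

#' Uniform material model (verification problems)
#' @param mesh A `sij_mesh`.
#' @param E Young's modulus (MPa).
#' @param poisson Poisson ratio.
#' @return A `material_model` with a single class.
#' @export
uniform_material <- function(mesh, E, poisson = 0.3) {
  m <- nrow(mesh$elems)
  structure(list(E = rep(E, m), E_raw = rep(E, m), class = rep.int(1L, m),
                 representatives = E, nu = poisson, n_classes = 1L),
            class = "material_model")
}
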