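# Load scenarios: the eight generic cases (uniaxial and combined extreme
# gait-load components, unilateral or bilaterally symmetric) and quasi-static
# gait-phase loads extracted from a (synthetic or user-supplied) hip joint
# force curve.

#' Define a load case
#'
#' Forces are per-side vectors in the local hip frames (x medio-lateral,
#' y antero-posterior, z cranial-caudal; the left frame mirrors x so equal
#' components give a mirror-symmetric load).
#'
#' @param name Scenario name.
#' @param force Length-3 force vector (N).
#' @param sides `"both"`, `"left_only"` or `"right_only"`.
#' @param scale Body-weight scale factor (> 0).
#' @return A `load_case`.
#' @export
load_case <- function(name, force, sides = "both", scale = 1) {
  if (scale <= 0) stop2("load scale must be > 0")
  if (length(force) != 3L) stop2("force must be a 3-vector")
  structure(list(name = name, force = as.numeric(force), sides = sides,
                 scale = scale), class = "load_case")
}

#' The eight generic load scenarios
#'
#' Extreme gait-load components Fx = 600 N (medio-lateral), Fy = 1200 N
#' (antero-posterior), Fz = 2400 N (cranial-caudal), applied uniaxially or
#' combined, unilaterally (left side) or bilaterally symmetric.
#'
#' @param fx,fy,fz Component magnitudes (N).
#' @return Named list of 8 [load_case()]s.
#' @export
generic_scenarios <- function(fx = 600, fy = 1200, fz = 2400) {
  list(
    unilateral_x = load_case("unilateral_x", c(fx, 0, 0), "left_only"),
    unilateral_y = load_case("unilateral_y", c(0, fy, 0), "left_only"),
    unilateral_z = load_case("unilateral_z", c(0, 0, fz), "left_only"),
    symmetric_x = load_case("symmetric_x", c(fx, 0, 0), "both"),
    symmetric_y = load_case("symmetric_y", c(0, fy, 0), "both"),
    symmetric_z = load_case("symmetric_z", c(0, 0, fz), "both"),
    unilateral_xyz = load_case("unilateral_xyz", c(fx, fy, fz), "left_only"),
    symmetric_xyz = load_case("symmetric_xyz", c(fx, fy, fz), "both")
  )
}

#' The five gait phases
#' @return Character vector: IHS, CTO, swing, CHS, ITO.
#' @export
gait_phases <- function() c("IHS", "CTO", "swing", "CHS", "ITO")

#' Synthetic gait force curve
#'
#' Smooth, seeded, periodic 3-component hip force curve over one gait cycle
#' whose per-component absolute maxima equal the given peaks exactly. Event
#' markers locate the five phases (ipsilateral heel strike, contralateral toe
#' off, swing, contralateral heel strike, ipsilateral toe off) at the extreme
#' |Fz| sample inside each phase window. This is a surrogate wave form: only
#' the printed peak magnitudes anchor it, not any measured trial.
#'
#' @param seed Integer seed for the wave-form perturbation.
#' @param peaks Per-component force peaks (N), default `c(600, 1200, 2400)`.
#' @return A `gait_curve`: data frame `samples` (`time_pct, fx_n, fy_n,
#'   fz_n`) and named integer `events` (sample indices of the phases).
#' @export
synth_gait <- function(seed = 0L, peaks = c(600, 1200, 2400)) {
  if (any(peaks <= 0)) stop2("peaks must be > 0")
  t <- seq(0, 100, by = 0.5)
  tt <- t / 100
  set.seed(as.integer(seed))
  perturb <- function() {
    a <- rnorm(3, sd = 0.04)
    a[1] * sin(2 * pi * tt) + a[2] * sin(4 * pi * tt) + a[3] * cos(6 * pi * tt)
  }
  # stance-dominated double-hump shape (loading response + push-off)
  stance <- ifelse(t <= 62, sin(pi * t / 62), 0)
  hump <- ifelse(t <= 62, 1 + 0.35 * cos(2 * pi * t / 62), 0.05)
  base_z <- stance * hump
  base_y <- stance * (0.8 + 0.4 * sin(pi * t / 62))
  base_x <- stance * (0.9 + 0.2 * cos(pi * t / 62))
  shape <- list(x = base_x + perturb(), y = base_y + perturb(), z = base_z + perturb())
  comp <- mapply(function(s, p) p * s / max(abs(s)), shape, peaks, SIMPLIFY = FALSE)
  samples <- data.frame(time_pct = t, fx_n = comp$x, fy_n = comp$y, fz_n = comp$z)
  windows <- list(IHS = c(0, 10), CTO = c(10, 25), swing = c(25, 45),
                  CHS = c(45, 58), ITO = c(58, 70))
  events <- vapply(windows, function(w) {
    idx <- which(t >= w[1] & t <= w[2])
    idx[which.max(abs(samples$fz_n[idx]))]
  }, integer(1))
  structure(list(samples = samples, events = events, peaks = peaks),
            class = "gait_curve")
}

#' @export
print.gait_curve <- function(x, ...) {
  cat(sprintf("Gait curve: %d samples, peaks (%.0f, %.0f, %.0f) N, events: %s\n",
              nrow(x$samples), x$peaks[1], x$peaks[2], x$peaks[3],
              paste(sprintf("%s@%.1f%%", names(x$events),
                            x$samples$time_pct[x$events]), collapse = ", ")))
  invisible(x)
}

#' Write a gait curve to CSV
#' @param curve A `gait_curve`.
#' @param path Output path (`time_pct,fx_n,fy_n,fz_n` plus a `phase` column
#'   marking event samples).
#' @export
write_gait_csv <- function(curve, path) {
  df <- curve$samples
  df$phase <- ""
  df$phase[curve$events] <- names(curve$events)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gait curve from CSV
#'
#' Expects columns `time_pct`, `fx_n`, `fy_n`, `fz_n` (forces in N); an
#' optional `phase` column marks event samples, otherwise events are
#' detected from |Fz| extremes within the standard phase windows.
#'
#' @param path CSV path.
#' @return A `gait_curve`.
#' @export
load_gait_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_pct", "fx_n", "fy_n", "fz_n")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop2("gait CSV missing column(s): %s",
                             paste(missing, collapse = ", "))
  events <- NULL
  if ("phase" %in% names(df)) {
    ev <- which(nzchar(df$phase) & !is.na(df$phase))
    if (length(ev)) events <- setNames(as.integer(ev), df$phase[ev])
  }
  if (is.null(events) || !all(gait_phases() %in% names(events))) {
    windows <- list(IHS = c(0, 10), CTO = c(10, 25), swing = c(25, 45),
                    CHS = c(45, 58), ITO = c(58, 70))
    events <- vapply(windows, function(w) {
      idx <- which(df$time_pct >= w[1] & df$time_pct <= w[2])
      if (!length(idx)) return(NA_integer_)
      idx[which.max(abs(df$fz_n[idx]))]
    }, integer(1))
    events <- events[!is.na(events)]
  }
  structure(list(samples = df[need], events = events,
                 peaks = vapply(df[c("fx_n", "fy_n", "fz_n")],
                                function(v) max(abs(v)), numeric(1))),
            class = "gait_curve")
}

#' Extract the five quasi-static phase load cases from a gait curve
#'
#' One static force vector per phase, read at the marked event sample; the
#' ipsilateral (left) side is loaded, the contralateral side is unloaded by
#' default or mirrored if requested.
#'
#' @param curve A `gait_curve`.
#' @param contralateral `"unloaded"` or `"mirrored"`.
#' @return Named list of 5 [load_case()]s.
#' @export
extract_phase_loads <- function(curve, contralateral = c("unloaded", "mirrored")) {
  contralateral <- match.arg(contralateral)
  missing <- setdiff(gait_phases(), names(curve$events))
  if (length(missing)) stop2("unmarked gait events: %s", paste(missing, collapse = ", "))
  out <- lapply(gait_phases(), function(ph) {
    i <- curve$events[[ph]]
    f <- as.numeric(curve$samples[i, c("fx_n", "fy_n", "fz_n")])
    load_case(paste0("gait_", ph), f,
              sides = if (contralateral == "mirrored") "both" else "left_only")
  })
  setNames(out, gait_phases())
}
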