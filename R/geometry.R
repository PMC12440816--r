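#' Loading geometry of a two-origin template
#'
#' Describes a linear DNA template carrying two ORC binding sites in
#' head-to-head orientation, each of which loads one MCM single hexamer (SH)
#' with the N-termini facing each other. The separation is measured between
#' the 5' ends of the two ORC binding sites. ORC engages 6 bp of DNA ahead of
#' its binding site and the loaded SH ring occupies a further 35 bp, so one
#' loaded SH+ORC takes up `orc_overhang + sh_footprint` = 41 bp past the
#' origin, and the two SHs cannot be loaded closer than 82 bp apart
#' (6 + 35 + 35 + 6).
#'
#' Coordinates place the left ORC 5' end at 0 and the right one at
#' `separation`; the left SH N-terminus starts at
#' `orc_overhang + sh_footprint`, the right one mirrored, so the initial
#' N-terminus-to-N-terminus gap is `separation - 2 * (orc_overhang +
#' sh_footprint)`.
#'
#' @param separation Distance in bp between the 5' ends of the two opposed
#'   ORC binding sites. Must be at least [closest_loading_separation()].
#' @param orc_overhang bp of DNA ORC engages ahead of its binding site
#'   (default 6).
#' @param sh_footprint bp occupied by one loaded MCM-SH ring (default 35).
#' @param template_length Total template length in bp, or `Inf` for an
#'   unbounded line (the default). Only used in reflecting boundary mode;
#'   the template is centered on the origin pair.
#' @param boundary_mode `"unbounded"` (default) or `"reflecting"`; reflecting
#'   mode folds SH N-terminus positions back at the template ends.
#' @return An object of class `template_geometry` with the fields above plus
#'   the derived `initial_gap`, initial N-terminus positions `x1_0`/`x2_0`,
#'   and template bounds `t_lo`/`t_hi`.
#' @examples
#' geom <- template_geometry(300)
#' geom$initial_gap # 218
#' @export
template_geometry <- function(separation,
                              orc_overhang = 6,
                              sh_footprint = 35,
                              template_length = Inf,
                              boundary_mode = c("unbounded", "reflecting")) {
  boundary_mode <- match.arg(boundary_mode)
  stopifnot(is.numeric(separation), length(separation) == 1L,
            orc_overhang >= 0, sh_footprint >= 0, template_length > 0)
  min_sep <- 2 * (orc_overhang + sh_footprint)
  if (separation < min_sep) {
    stop("separation ", separation, " bp is below the closest possible ",
         "loading separation of ", min_sep, " bp (two SHs cannot be loaded ",
         "closer)", call. = FALSE)
  }
  if (boundary_mode == "reflecting") {
    if (!is.finite(template_length))
      stop("reflecting boundary mode requires a finite template_length",
           call. = FALSE)
    if (template_length < separation)
      stop("template_length must be at least the site separation",
           call. = FALSE)
  }
  margin <- if (is.finite(template_length)) (template_length - separation) / 2 else Inf
  structure(
    list(
      separation = separation,
      orc_overhang = orc_overhang,
      sh_footprint = sh_footprint,
      template_length = template_length,
      boundary_mode = boundary_mode,
      initial_gap = separation - min_sep,
      x1_0 = orc_overhang + sh_footprint,
      x2_0 = separation - (orc_overhang + sh_footprint),
      t_lo = -margin,
      t_hi = separation + margin
    ),
    class = "template_geometry"
  )
}

#' @export
print.template_geometry <- function(x, ...) {
  cat("Two-origin loading geometry\n")
  cat("  separation:        ", x$separation, "bp (5' end to 5' end)\n")
  cat("  ORC overhang:      ", x$orc_overhang, "bp\n")
  cat("  SH footprint:      ", x$sh_footprint, "bp\n")
  cat("  initial SH gap:    ", x$initial_gap, "bp\n")
  cat("  boundary mode:     ", x$boundary_mode,
      if (is.finite(x$template_length))
        paste0(" (template ", x$template_length, " bp)") else "", "\n",
      sep = "")
  invisible(x)
}

#' Closest possible separation between two loaded SHs
#'
#' The minimal distance between the 5' ends of two opposed ORC binding sites
#' at which both can still load an SH: ORC overhang + SH footprint + SH
#' footprint + ORC overhang. With the default constants this is
#' 6 + 35 + 35 + 6 = 82 bp, the separation at which the two loaded SHs are
#' already touching.
#'
#' @param orc_overhang,sh_footprint Footprint constants in bp; a
#'   `template_geometry` may be passed as the first argument instead.
#' @return Separation in bp.
#' @examples
#' closest_loading_separation() # 82
#' @export
closest_loading_separation <- function(orc_overhang = 6, sh_footprint = 35) {
  if (inherits(orc_overhang, "template_geometry")) {
    g <- orc_overhang
    orc_overhang <- g$orc_overhang
    sh_footprint <- g$sh_footprint
  }
  stopifnot(orc_overhang >= 0, sh_footprint >= 0)
  2 * (orc_overhang + sh_footprint)
}

#' Initial N-terminus-to-N-terminus gap of two loaded SHs
#'
#' @param separation Distance in bp between the 5' ends of the two ORC sites.
#' @param orc_overhang,sh_footprint Footprint constants in bp; a
#'   `template_geometry` may be passed instead of `orc_overhang`.
#' @return Gap in bp; errors when the separation is below the loading minimum.
#' @examples
#' initial_gap(300) # 218
#' @export
initial_gap <- function(separation, orc_overhang = 6, sh_footprint = 35) {
  if (inherits(orc_overhang, "template_geometry")) {
    g <- orc_overhang
    orc_overhang <- g$orc_overhang
    sh_footprint <- g$sh_footprint
  }
  min_sep <- closest_loading_separation(orc_overhang, sh_footprint)
  if (any(separation < min_sep)) {
    stop("separation below the closest loading separation of ", min_sep,
         " bp", call. = FALSE)
  }
  separation - min_sep
}

#' Largest time step keeping the per-step MSD below a cap
#'
#' The one-dimensional mean squared displacement per step is `2 * D * dt`
#' (in bp^2), so the largest admissible step under a cap `msd_cap` is
#' `msd_cap / (2 * D)`. In `"fidelity"` mode the historical fixed choice of
#' 10 microseconds is returned instead, regardless of the cap.
#'
#' @param D Diffusion coefficient in bp^2/s.
#' @param msd_cap Per-step MSD cap in bp^2 (default 1).
#' @param mode `"cap"` (solve `2 D dt = msd_cap`) or `"fidelity"` (fixed
#'   1e-5 s).
#' @param dt_max Ceiling returned (with a warning) when `D = 0`.
#' @return Time step in seconds.
#' @examples
#' choose_time_step(800) # 0.000625
#' @export
choose_time_step <- function(D, msd_cap = 1, mode = c("cap", "fidelity"),
                             dt_max = 1e-2) {
  mode <- match.arg(mode)
  stopifnot(D >= 0, msd_cap > 0, dt_max > 0)
  if (mode == "fidelity") return(1e-5)
  if (D == 0) {
    warning("D = 0: no motion, returning dt_max")
    return(dt_max)
  }
  msd_cap / (2 * D)
}
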