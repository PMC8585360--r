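#' Conical single-point diamond tool geometry
#'
#' Describes the conical diamond tip used to plough microgrooves.  The
#' working angle is `phi`, the angle between the cone side and the
#' workpiece plane; for a cone with full included angle `cone_angle` it is
#' `phi = 90 - cone_angle / 2`.  The reference tool has a 90 degree cone,
#' hence `phi = 45` and `tan(phi) = 1`.
#'
#' @param cone_angle Full included angle of the conical tip, degrees.
#' @param tip_diameter Diameter of the diamond tip, mm.
#' @param shank_diameter,bit_diameter Optional shank/bit diameters, mm
#'   (descriptive only; they do not enter any force law).
#'
#' @return An object of class `"tool_geometry"`: a list with elements
#'   `cone_angle`, `phi` (degrees), `tan_phi`, `tip_diameter`,
#'   `shank_diameter`, `bit_diameter`.
#' @examples
#' tool <- tool_geometry()
#' tool$phi       # 45
#' tool$tan_phi   # 1
#' @seealso [indentation_volume()], [indentation_state()]
#' @export
tool_geometry <- function(cone_angle = 90, tip_diameter = 2,
                          shank_diameter = 9.7, bit_diameter = 11) {
  stopifnot(is.numeric(cone_angle), length(cone_angle) == 1L,
            is.numeric(tip_diameter), length(tip_diameter) == 1L)
  phi <- 90 - cone_angle / 2
  if (!(phi > 0 && phi < 90))
    stop("'cone_angle' must lie in (0, 180) so that 0 < phi < 90", call. = FALSE)
  if (tip_diameter <= 0) stop("'tip_diameter' must be positive", call. = FALSE)
  structure(list(cone_angle = cone_angle, phi = phi,
                 tan_phi = tan(phi * pi / 180),
                 tip_diameter = tip_diameter,
                 shank_diameter = shank_diameter,
                 bit_diameter = bit_diameter),
            class = "tool_geometry")
}

#' @export
print.tool_geometry <- function(x, ...) {
  cat("Conical SPDT geometry\n")
  cat(sprintf("  cone angle: %g deg (phi = %g deg, tan phi = %.6g)\n",
              x$cone_angle, x$phi, x$tan_phi))
  cat(sprintf("  tip diameter: %g mm\n", x$tip_diameter))
  invisible(x)
}

#' Cortical bone material properties
#'
#' Mechanical parameters of cortical bone entering the physical force laws.
#' Defaults describe bovine femoral cortical bone: Young's modulus in the
#' reported 10--22 GPa range (15 GPa = 15000 MPa used as the working
#' value), a yield strength at the top of the reported compressive-strength
#' range, and an inherent shear strength of 3 MPa.
#'
#' @param E Elastic (Young's) modulus, MPa.
#' @param delta_s Yield strength, MPa.
#' @param tau_s Inherent shear strength, MPa.
#' @param properties Optional named list of further descriptive properties
#'   (tensile/compressive strength ranges, density, Poisson ratio, ...).
#'
#' @return An object of class `"bone_material"`.
#' @examples
#' bone_material()
#' bone_material(E = 18000, delta_s = 120)
#' @export
bone_material <- function(E = 15000, delta_s = 150, tau_s = 3,
                          properties = list()) {
  for (nm in c("E", "delta_s", "tau_s")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive number", nm), call. = FALSE)
  }
  structure(list(E = E, delta_s = delta_s, tau_s = tau_s,
                 properties = properties),
            class = "bone_material")
}

#' @export
print.bone_material <- function(x, ...) {
  cat("Cortical bone material\n")
  cat(sprintf("  E = %g MPa, yield strength = %g MPa, shear strength = %g MPa\n",
              x$E, x$delta_s, x$tau_s))
  invisible(x)
}

#' Volume of the conical tip pressed into the bone
#'
#' For a cone ploughing at uncut chip thickness (depth) `h` the indented
#' volume is \eqn{V = \pi h^3 / (3 \tan^2 \varphi)}, which reduces to
#' \eqn{\pi h^3 / 3} for the 90 degree reference cone (`tan(phi) = 1`).
#'
#' @param h Uncut chip thickness, mm.  Vectorised; must be nonnegative.
#' @param tool A [tool_geometry()].
#' @return Indented volume, mm^3.
#' @examples
#' indentation_volume(0.7)            # pi * 0.7^3 / 3
#' indentation_volume(c(0.5, 0.8))
#' @export
indentation_volume <- function(h, tool = tool_geometry()) {
  check_depth(h)
  pi * h^3 / (3 * tool$tan_phi^2)
}

#' Indentation geometry at a given depth
#'
#' Deterministic geometric state of the cone/bone contact at uncut chip
#' thickness `h`: the indented volume `V`, the horizontal projected contact
#' area `A` (the area entering the yield-force law,
#' \eqn{A = \pi h^2 / (8 \tan^2 \varphi)}), the forward projected area
#' `A_p = h^2 / tan(phi)` swept by the advancing flank, and the indentation
#' diameter `d = 2 h tan(phi)`.
#'
#' @inheritParams indentation_volume
#' @return A data frame with columns `h`, `V`, `A`, `A_p`, `d`.
#' @examples
#' indentation_state(c(0.5, 0.6, 0.7, 0.8))
#' @export
indentation_state <- function(h, tool = tool_geometry()) {
  check_depth(h)
  tp <- tool$tan_phi
  data.frame(h = h,
             V = pi * h^3 / (3 * tp^2),
             A = pi * h^2 / (8 * tp^2),
             A_p = h^2 / tp,
             d = 2 * h * tp)
}

check_depth <- function(h) {
  if (!is.numeric(h) || any(!is.finite(h)) || any(h < 0))
    stop("depth 'h' must be numeric, finite and nonnegative", call. = FALSE)
  invisible(h)
}
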