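#' Physical normal-force laws for conical indentation of cortical bone
#'
#' Three closed-form laws for the normal force `F_z` exerted by a rigid
#' cone pressed to depth `h` into cortical bone:
#'
#' * `elastic_normal_force()` — the conical-contact (Sneddon) force on an
#'   elastic half-space, \eqn{F_z = (2/\pi)\, E\, h^2 \tan\varphi};
#'   quadratic in depth.
#' * `yield_normal_force()` — once the contact yields, force is carried at
#'   the yield strength over the horizontal projected area,
#'   \eqn{F_z = \delta_s A = \pi h^2 \delta_s / (8 \tan^2\varphi)}.
#' * `integrated_normal_force()` — the depth-integrated yield law,
#'   \eqn{F_z = \int_0^h A\, \delta_s \, dh = \pi \delta_s h^3 /
#'   (24 \tan^2 \varphi) = \delta_s V / (8 \tan^2 \varphi)} with `V` the
#'   indented volume; cubic in depth.
#'
#' `elastic_force_from_area()` is the intermediate area form
#' \eqn{F_z = (\tan\varphi / 2)\, E\, A}; it is retained for completeness
#' of the derivation and is not used by any other routine.
#'
#' All are vectorised over `h` (or `A`).
#'
#' @param h Uncut chip thickness (depth), mm; nonnegative.
#' @param A Contact area, mm^2; nonnegative.
#' @param mat A [bone_material()].
#' @param tool A [tool_geometry()].
#' @return Normal force, N.
#' @examples
#' elastic_normal_force(0.5, bone_material(E = 15000))   # (2/pi)*15000*0.25
#' yield_normal_force(0.5, bone_material(delta_s = 150))
#' integrated_normal_force(0.5, bone_material(delta_s = 150))
#' @name contact_forces
NULL

#' @rdname contact_forces
#' @export
elastic_normal_force <- function(h, mat = bone_material(),
                                 tool = tool_geometry()) {
  check_depth(h)
  (2 / pi) * mat$E * h^2 * tool$tan_phi
}

#' @rdname contact_forces
#' @export
elastic_force_from_area <- function(A, mat = bone_material(),
                                    tool = tool_geometry()) {
  if (!is.numeric(A) || any(!is.finite(A)) || any(A < 0))
    stop("'A' must be numeric, finite and nonnegative", call. = FALSE)
  (tool$tan_phi / 2) * mat$E * A
}

#' @rdname contact_forces
#' @export
yield_normal_force <- function(h, mat = bone_material(),
                               tool = tool_geometry()) {
  check_depth(h)
  mat$delta_s * pi * h^2 / (8 * tool$tan_phi^2)
}

#' @rdname contact_forces
#' @export
integrated_normal_force <- function(h, mat = bone_material(),
                                    tool = tool_geometry()) {
  check_depth(h)
  pi * mat$delta_s * h^3 / (24 * tool$tan_phi^2)
}
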