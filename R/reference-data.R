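#' Bundled replicate measurements from the cutting experiments
#'
#' Two small datasets transcribed from the reference orthogonal-cutting
#' experiments on bovine femoral cortical bone, used to calibrate and
#' check the models:
#'
#' * `plough_coefficients()` — the fifteen replicate ploughing
#'   coefficients measured at 0.7 mm uncut chip thickness, five
#'   replicates at each cutting angle 0/45/90 degrees.  Columns:
#'   `theta_deg`, `replicate`, `fp`.
#' * `tangential_forces()` — replicate mean tangential forces for the
#'   remaining factorial cells (uncut chip thickness 0.5/0.6/0.8 mm
#'   crossed with angles 0/45/90 degrees, five replicates).  Columns:
#'   `h_mm`, `theta_deg`, `replicate`, `fp_n`.
#'
#' @return A data frame.
#' @examples
#' d <- plough_coefficients()
#' tapply(d$fp, d$theta_deg, mean)
#' @name reference_data
#' @export
plough_coefficients <- function() {
  utils::read.csv(system.file("extdata", "ploughing_coefficients.csv",
                              package = "boneplough", mustWork = TRUE))
}

#' @rdname reference_data
#' @export
tangential_forces <- function() {
  utils::read.csv(system.file("extdata", "tangential_forces.csv",
                              package = "boneplough", mustWork = TRUE))
}
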